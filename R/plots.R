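#' Plot a grid-convergence report
#'
#' Relative errors of the total, glucose-utilizer and acetate-utilizer
#' volumes against the reference resolution, on log-log axes.
#'
#' @param report Tibble from [convergence_report()].
#' @return A ggplot.
#' @export
plot_convergence <- function(report) {
  df <- tidyr::pivot_longer(
    dplyr::select(report, "dx_um", "err_total", "err_glu", "err_ace"),
    -"dx_um", names_to = "quantity", values_to = "error")
  df <- df[df$error > 0, ]
  labs <- c(err_total = "total volume", err_glu = "glucose utilizers",
            err_ace = "acetate utilizers")
  df$quantity <- labs[df$quantity]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dx_um, y = .data$error,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.05, 0.025),
                        linetype = c("solid", "dashed"), colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "grid resolution (um)",
                  y = "relative error vs reference",
                  colour = NULL)
}

#' Plot axis concentration profiles
#'
#' Depth-vs-concentration curves through the colony's central axis for one or
#' more species, in the orientation conventional for colony cross-sections
#' (depth on the vertical axis, zero at the agar surface).
#'
#' @param state A `lattice_state`.
#' @param species Character vector of species names (default: all).
#' @return A ggplot.
#' @export
plot_axis_profile <- function(state, species = names(state$conc)) {
  df <- dplyr::bind_rows(lapply(species, function(sp) {
    pr <- axis_profile(state, sp)
    pr$species <- sp
    pr
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_mM, y = .data$depth_um)) +
    ggplot2::geom_path() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~species, scales = "free_x") +
    ggplot2::labs(x = "concentration (mM)",
                  y = "depth relative to agar surface (um)")
}
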