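#' @title Flux lookup tables
#' @description
#' The simulator never solves a linear program during time stepping. Instead
#' each phenotype carries a precomputed table of FBA solutions indexed by
#' (carbon-source uptake, oxygen uptake); at run time the engine interpolates
#' the table at the locally available uptake rates. Tables can be built from a
#' genome-scale (or toy) metabolic model by solving one LP per node
#' ([build_flux_table()]) or from a strain record via a closed-form surrogate
#' anchored to the measured aerobic/anaerobic growth and acetate rates
#' ([build_surrogate_table()]).
#' @name flux-tables
NULL

#' Phenotype identifiers
#'
#' Exactly two metabolic phenotypes are modeled: cells growing on glucose
#' (aerobically or fermentatively) and cells growing aerobically on acetate.
#'
#' @return Character vector of the two phenotype ids.
#' @export
phenotypes <- function() c("GLUCOSE_UTILIZER", "ACETATE_UTILIZER")

match_phenotype <- function(phenotype) {
  match.arg(phenotype, phenotypes())
}

new_flux_table <- function(phenotype, strain, carbon_axis, o2_axis, grids,
                           source, record = NULL, params = NULL) {
  structure(
    list(
      phenotype = phenotype,
      strain = strain,
      carbon_axis = carbon_axis,  # uptake magnitudes, mmol/gDCW/hr
      o2_axis = o2_axis,
      grids = grids,              # named list of length(carbon) x length(o2) matrices
      source = source,            # "surrogate" or "model"
      record = record,
      params = params
    ),
    class = "flux_table"
  )
}

#' @export
print.flux_table <- function(x, ...) {
  cat("<flux_table> ", x$phenotype, " (", x$source, ")",
      if (!is.null(x$strain)) paste0(" strain ", x$strain), "\n", sep = "")
  cat("  carbon axis: ", length(x$carbon_axis), " nodes in [0, ",
      format(max(x$carbon_axis)), "] mmol/gDCW/hr\n", sep = "")
  cat("  O2 axis:     ", length(x$o2_axis), " nodes in [0, ",
      format(max(x$o2_axis)), "] mmol/gDCW/hr\n", sep = "")
  cat("  quantities:  ", paste(names(x$grids), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the surrogate flux model in closed form
#'
#' The surrogate blends a fully aerobic and a fully anaerobic operating mode
#' of a strain, anchored to its measured rates. For the glucose utilizer:
#' aerobic capacity `a = v_glc_aero`, anaerobic capacity `n = v_glc_anaero`;
#' the oxygen demand of aerobic operation at glucose uptake `g` is
#' `v_o2_max * min(g, a)/a` and the oxygen-sufficiency fraction is
#' `f = min(1, o2 / demand)`. Growth and acetate efflux are linear in carbon
#' uptake within each mode and blended by `f`:
#' `v_bm = f * mu_aero * min(g,a)/a + (1-f) * mu_anaero * min(g,n)/n`.
#' At the aerobic anchor (`g = v_glc_aero`, ample oxygen) this returns exactly
#' (`mu_aero`, `v_ac_aero`); at the anaerobic anchor (`g = v_glc_anaero`,
#' no oxygen) exactly (`mu_anaero`, `v_ac_anaero`).
#'
#' The acetate utilizer grows strictly aerobically: uptake is capped at
#' `ac_uptake_max`, oxygen demand is `o2_per_ac` per acetate, growth is
#' `ac_yield` per unit of realized (oxygen-sufficient) acetate uptake, and
#' growth is zero without oxygen.
#'
#' @param record One-row strain record (see [ecoli_strains()]).
#' @param phenotype `"GLUCOSE_UTILIZER"` or `"ACETATE_UTILIZER"`.
#' @param carbon Vector of available carbon-source uptake rates
#'   (glucose for the glucose utilizer, acetate for the acetate utilizer),
#'   magnitudes in mmol/gDCW/hr.
#' @param o2 Vector of available oxygen uptake rates, mmol/gDCW/hr.
#' @param ac_uptake_max Maximal acetate uptake of the acetate phenotype,
#'   mmol/gDCW/hr. Strain-specific uptake data are unavailable, so a single
#'   configurable ceiling is used.
#' @param ac_yield Biomass yield on acetate, gDCW per mmol acetate.
#' @param ac_o2_per_ac Oxygen demand of acetate catabolism, mol O2 per mol
#'   acetate.
#' @return Tibble with columns `v_bm` (1/hr), `v_glc`, `v_ac`, `v_o2`
#'   (mmol/gDCW/hr; uptake negative, secretion positive).
#' @export
surrogate_fluxes <- function(record, phenotype, carbon, o2,
                             ac_uptake_max = 10, ac_yield = 0.025,
                             ac_o2_per_ac = 2) {
  phenotype <- match_phenotype(phenotype)
  validate_strain_record(record)
  stopifnot(length(carbon) == length(o2) || length(carbon) == 1 || length(o2) == 1)
  n <- max(length(carbon), length(o2))
  carbon <- rep_len(pmax(carbon, 0), n)
  o2 <- rep_len(pmax(o2, 0), n)
  if (phenotype == "GLUCOSE_UTILIZER") {
    a <- record$v_glc_aero
    n <- record$v_glc_anaero
    ga <- pmin(carbon, a)           # glucose processed in the aerobic mode
    gn <- pmin(carbon, n)           # ... in the anaerobic mode
    demand <- record$v_o2_max * ga / a
    f <- ifelse(demand > 0, pmin(1, o2 / demand), 1)
    v_bm <- f * record$mu_aero * ga / a + (1 - f) * record$mu_anaero * gn / n
    v_ac <- f * record$v_ac_aero * ga / a + (1 - f) * record$v_ac_anaero * gn / n
    v_glc <- -(f * ga + (1 - f) * gn)
    v_o2 <- -pmin(o2, demand)
  } else {
    u <- pmin(carbon, ac_uptake_max)
    demand <- ac_o2_per_ac * u
    f <- ifelse(demand > 0, pmin(1, o2 / demand), 1)
    u_eff <- f * u                  # acetate growth is aerobic only
    v_bm <- ac_yield * u_eff
    v_ac <- -u_eff
    v_glc <- rep(0, length(u_eff))
    v_o2 <- -pmin(o2, demand)
  }
  tibble::tibble(v_bm = v_bm, v_glc = v_glc, v_ac = v_ac, v_o2 = v_o2)
}

#' Build a surrogate flux table from a strain record
#'
#' Samples [surrogate_fluxes()] on a regular (carbon, oxygen) uptake grid with
#' the standard table dimensions: `n_carbon` evenly spaced nodes between 0 and
#' the maximal carbon uptake and `n_o2` nodes between 0 and the maximal oxygen
#' uptake.
#'
#' @inheritParams surrogate_fluxes
#' @param n_carbon,n_o2 Number of axis divisions (defaults 50 and 160).
#' @return A `flux_table`.
#' @export
#' @examples
#' ft <- build_surrogate_table(strain_record("MG1655"), "GLUCOSE_UTILIZER")
#' lookup_fluxes(ft, glc = 9.5, o2 = 13.9)
build_surrogate_table <- function(record, phenotype, n_carbon = 50, n_o2 = 160,
                                  ac_uptake_max = 10, ac_yield = 0.025,
                                  ac_o2_per_ac = 2) {
  phenotype <- match_phenotype(phenotype)
  validate_strain_record(record)
  carbon_max <- if (phenotype == "GLUCOSE_UTILIZER") {
    max(record$v_glc_aero, record$v_glc_anaero)
  } else {
    ac_uptake_max
  }
  carbon_axis <- seq(0, carbon_max, length.out = n_carbon)
  o2_axis <- seq(0, record$v_o2_max, length.out = n_o2)
  nodes <- expand.grid(carbon = carbon_axis, o2 = o2_axis)
  fl <- surrogate_fluxes(record, phenotype, nodes$carbon, nodes$o2,
                         ac_uptake_max = ac_uptake_max, ac_yield = ac_yield,
                         ac_o2_per_ac = ac_o2_per_ac)
  grids <- lapply(fl, function(v) matrix(v, nrow = n_carbon, ncol = n_o2))
  new_flux_table(phenotype, record$strain, carbon_axis, o2_axis, grids,
                 source = "surrogate", record = record,
                 params = list(ac_uptake_max = ac_uptake_max,
                               ac_yield = ac_yield,
                               ac_o2_per_ac = ac_o2_per_ac))
}

# Vectorized bilinear interpolation on a regular grid; queries are clamped to
# the axis ranges (queries beyond an axis maximum return the edge values).
interp_bilinear <- function(grid, x_axis, y_axis, x, y) {
  nx <- length(x_axis)
  ny <- length(y_axis)
  x <- pmin(pmax(x, x_axis[1]), x_axis[nx])
  y <- pmin(pmax(y, y_axis[1]), y_axis[ny])
  i <- pmin(pmax(findInterval(x, x_axis), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(y, y_axis), 1L), ny - 1L)
  tx <- (x - x_axis[i]) / (x_axis[i + 1L] - x_axis[i])
  ty <- (y - y_axis[j]) / (y_axis[j + 1L] - y_axis[j])
  g00 <- grid[cbind(i, j)]
  g10 <- grid[cbind(i + 1L, j)]
  g01 <- grid[cbind(i, j + 1L)]
  g11 <- grid[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * g00 + tx * (1 - ty) * g10 +
    (1 - tx) * ty * g01 + tx * ty * g11
}

#' Interpolate a flux table at available uptake rates
#'
#' Availabilities are clamped to the table axis ranges and each stored
#' quantity is interpolated bilinearly between the four surrounding nodes.
#'
#' @param table A `flux_table`.
#' @param glc Available carbon-source uptake rate(s), mmol/gDCW/hr
#'   (glucose or acetate depending on the table's phenotype).
#' @param o2 Available oxygen uptake rate(s), mmol/gDCW/hr.
#' @return Tibble with one row per query and columns `v_bm`, `v_glc`, `v_ac`,
#'   `v_o2`.
#' @export
lookup_fluxes <- function(table, glc, o2) {
  stopifnot(inherits(table, "flux_table"))
  if (any(glc < 0) || any(o2 < 0)) {
    stop("availabilities must be >= 0", call. = FALSE)
  }
  out <- lapply(table$grids, interp_bilinear,
                x_axis = table$carbon_axis, y_axis = table$o2_axis,
                x = glc, y = o2)
  tibble::as_tibble(out)
}

#' Write a flux table as portable text
#'
#' Serializes the table as a long-format CSV (one row per grid node) plus a
#' JSON sidecar (`<path>.meta.json`) holding the axes, units, phenotype, and
#' provenance.
#'
#' @param table A `flux_table`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(table, path) {
  long <- expand.grid(i = seq_along(table$carbon_axis),
                      j = seq_along(table$o2_axis))
  df <- tibble::tibble(
    carbon_uptake = table$carbon_axis[long$i],
    o2_uptake = table$o2_axis[long$j]
  )
  for (q in names(table$grids)) df[[q]] <- table$grids[[q]][cbind(long$i, long$j)]
  readr::write_csv(df, path)
  meta <- list(
    phenotype = table$phenotype,
    strain = table$strain,
    source = table$source,
    units = list(axes = "mmol/gDCW/hr", v_bm = "1/hr",
                 exchange = "mmol/gDCW/hr (uptake negative)"),
    n_carbon = length(table$carbon_axis),
    n_o2 = length(table$o2_axis),
    params = table$params,
    record = if (!is.null(table$record)) as.list(table$record),
    package = as.character(utils::packageVersion("colonyfba"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a flux table written by [write_flux_table()]
#'
#' @param path CSV path (its `.meta.json` sidecar must sit next to it).
#' @return A `flux_table`.
#' @export
read_flux_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  carbon_axis <- sort(unique(df$carbon_uptake))
  o2_axis <- sort(unique(df$o2_uptake))
  qs <- setdiff(names(df), c("carbon_uptake", "o2_uptake"))
  i <- match(df$carbon_uptake, carbon_axis)
  j <- match(df$o2_uptake, o2_axis)
  grids <- lapply(qs, function(q) {
    g <- matrix(NA_real_, length(carbon_axis), length(o2_axis))
    g[cbind(i, j)] <- df[[q]]
    g
  })
  names(grids) <- qs
  record <- if (!is.null(meta$record)) tibble::as_tibble(meta$record)
  new_flux_table(meta$phenotype, meta$strain, carbon_axis, o2_axis, grids,
                 source = meta$source, record = record, params = meta$params)
}

#' Heatmap of a flux-table quantity
#'
#' @param object A `flux_table`.
#' @param quantity Which stored grid to draw (default growth rate).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flux_table <- function(object, quantity = "v_bm", ...) {
  long <- expand.grid(carbon = object$carbon_axis, o2 = object$o2_axis)
  long$value <- as.vector(object$grids[[quantity]])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$carbon, y = .data$o2,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = quantity) +
    ggplot2::labs(
      x = paste0(if (object$phenotype == "GLUCOSE_UTILIZER") "glucose" else "acetate",
                 " uptake (mmol/gDCW/hr)"),
      y = "O2 uptake (mmol/gDCW/hr)",
      title = paste0(object$phenotype, " (", object$source, ")")
    )
}
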