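#' Phenotype composition of a colony
#'
#' Mass fractions of the two phenotypes, plus the active-consumer share: the
#' fraction of acetate-utilizer mass whose applied acetate uptake was nonzero
#' at the last metabolic step.
#'
#' @param state A `lattice_state` with biomass.
#' @return Tibble with columns `phenotype`, `mass_fg`, `fraction`, and (for
#'   the acetate utilizer) `active_fraction`. With zero total biomass the
#'   fractions are `NA` (sentinel).
#' @export
phenotype_fractions <- function(state) {
  m_glu <- sum(state$biomass$GLUCOSE_UTILIZER)
  m_ace <- sum(state$biomass$ACETATE_UTILIZER)
  m_tot <- m_glu + m_ace
  active <- if (m_ace > 0 && !is.null(state$applied$ace_uptake)) {
    sum(state$biomass$ACETATE_UTILIZER[state$applied$ace_uptake < -1e-9]) / m_ace
  } else {
    NA_real_
  }
  tibble::tibble(
    phenotype = phenotypes(),
    mass_fg = c(m_glu, m_ace),
    fraction = if (m_tot > 0) c(m_glu, m_ace) / m_tot else rep(NA_real_, 2),
    active_fraction = c(NA_real_, active)
  )
}

#' Cross-feeding onset time
#'
#' First time the acetate-capable fraction crosses a threshold, linearly
#' interpolated between samples. Returns `NA` (sentinel) if the threshold is
#' never crossed.
#'
#' @param series Tibble (or data frame) with columns `time_hr` and `value`
#'   (the acetate-capable fraction).
#' @param threshold Fraction defining onset (default 1%).
#' @return Onset time, hr, or `NA`.
#' @export
#' @examples
#' onset_time(data.frame(time_hr = c(10, 11), value = c(0.005, 0.015)))  # 10.5
onset_time <- function(series, threshold = 0.01) {
  t <- series$time_hr
  v <- series$value
  stopifnot(length(t) == length(v), !is.unsorted(t))
  v[is.na(v)] <- 0
  at <- which(v >= threshold)
  if (length(at) == 0) return(NA_real_)
  k <- at[1]
  if (k == 1 || v[k] == threshold) return(t[k])
  t[k - 1] + (threshold - v[k - 1]) / (v[k] - v[k - 1]) * (t[k] - t[k - 1])
}

#' Colony height, width and aspect ratio
#'
#' Measures the bounding extents of the region where the total cell volume
#' fraction exceeds `colony_level * phi_max` (site-center membership).
#' Height is the vertical extent; width the larger caliper extent along the
#' two lateral axes.
#'
#' @param state A `lattice_state`.
#' @param colony_level Contour level as a fraction of the packing cap
#'   (default 0.64, the whole-colony contour).
#' @param feature_level Contour level for the acetate-utilizing region
#'   (reported as `feature_height_um`/`feature_width_um` when that region is
#'   non-empty), as a fraction of the packing cap.
#' @return One-row tibble with `height_um`, `width_um`, `aspect`, and the
#'   feature extents; `NA` sentinels when a region is empty.
#' @export
colony_dimensions <- function(state, colony_level = 0.64,
                              feature_level = 0.05) {
  stopifnot(colony_level > 0, colony_level < 1,
            feature_level > 0, feature_level < 1)
  dx <- state$dx
  extents <- function(mask) {
    if (!any(mask)) {
      return(list(height = NA_real_, width = NA_real_))
    }
    w <- which(mask, arr.ind = TRUE)
    list(
      height = (max(w[, 3]) - min(w[, 3]) + 1) * dx,
      width = max(max(w[, 1]) - min(w[, 1]) + 1,
                  max(w[, 2]) - min(w[, 2]) + 1) * dx
    )
  }
  phi <- phi_total(state)
  cap <- state$consts$phi_max
  whole <- extents(phi >= colony_level * cap)
  phi_ace <- state$biomass$ACETATE_UTILIZER /
    (site_volume(state) * state$consts$rho)
  feat <- extents(phi_ace >= feature_level * cap)
  tibble::tibble(
    height_um = whole$height, width_um = whole$width,
    aspect = if (!is.na(whole$height) && !is.na(whole$width) && whole$width > 0)
      whole$height / whole$width else NA_real_,
    feature_height_um = feat$height, feature_width_um = feat$width
  )
}

#' Concentration profile through the colony's central axis
#'
#' Samples a species along the vertical column through the seed site; depth
#' is reported relative to the agar surface in that column (negative below
#' the surface).
#'
#' @param state A `lattice_state` (seeded, so the central column is known; a
#'   `column` index `c(i, j)` may be supplied instead).
#' @param species_name Species to sample.
#' @param column Optional lateral site index.
#' @return Tibble with `depth_um` and `conc_mM`.
#' @export
axis_profile <- function(state, species_name, column = NULL) {
  if (is.null(column)) {
    if (is.null(state$seed_index)) {
      stop("state has no seed; supply `column`", call. = FALSE)
    }
    column <- state$seed_index[1:2]
  }
  i <- column[1]; j <- column[2]
  col_phase <- state$phase[i, j, ]
  k_agar <- which(col_phase == PHASE_AGAR)
  surface <- if (length(k_agar) > 0) max(k_agar) * state$dx else 0
  z <- (seq_len(state$dims[3]) - 0.5) * state$dx
  tibble::tibble(
    depth_um = z - surface,
    conc_mM = state$conc[[species_name]][i, j, ]
  )
}

#' Grid-convergence error against a reference trajectory
#'
#' Mean relative deviation of the total, glucose-utilizer and
#' acetate-utilizer colony volumes from a reference-resolution trajectory,
#' averaged over the common sample times in `[t0, t1]`. Also flags
#' non-physical oscillation of the acetate-capable fraction: at least three
#' sign changes of its discrete derivative with amplitude above 10% of the
#' series mean.
#'
#' @param traj,ref `colony_trajectory` objects (ref at the reference
#'   resolution).
#' @param t0,t1 Averaging window, hr.
#' @return One-row tibble: `dx_um`, `err_total`, `err_glu`, `err_ace`
#'   (relative), `oscillating`.
#' @export
convergence_error <- function(traj, ref, t0 = 10, t1 = 30) {
  common <- intersect(round(traj$series$time_hr, 9), round(ref$series$time_hr, 9))
  common <- common[common >= t0 & common <= t1]
  if (length(common) == 0) {
    stop("trajectories share no sample times in [", t0, ", ", t1, "] hr",
         call. = FALSE)
  }
  pick <- function(tr) tr$series[match(common, round(tr$series$time_hr, 9)), ]
  a <- pick(traj)
  b <- pick(ref)
  rel <- function(v, vr) mean(abs(v - vr) / ifelse(vr > 0, vr, NA_real_),
                              na.rm = TRUE)
  fr <- a$frac_ace
  fr[is.na(fr)] <- 0
  dfr <- diff(fr)
  sgn <- sign(dfr)
  changes <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  amp_ok <- abs(dfr) > 0.1 * mean(fr)
  n_osc <- sum(vapply(changes, function(k) amp_ok[k] || amp_ok[k + 1],
                      logical(1)))
  tibble::tibble(
    dx_um = traj$config$dx,
    err_total = rel(a$vol_total_fL, b$vol_total_fL),
    err_glu = rel(a$vol_glu_fL, b$vol_glu_fL),
    err_ace = rel(a$vol_ace_fL, b$vol_ace_fL),
    oscillating = is.finite(mean(fr)) && mean(fr) > 0 && n_osc >= 3
  )
}

#' Grid-convergence report over several resolutions
#'
#' Runs [convergence_error()] of every trajectory against the finest one.
#'
#' @param trajs List of `colony_trajectory` at different `dx`.
#' @param t0,t1 Averaging window, hr.
#' @return Tibble with one row per resolution (reference row has error 0),
#'   sorted coarse to fine.
#' @export
convergence_report <- function(trajs, t0 = 10, t1 = 30) {
  dxs <- vapply(trajs, function(tr) tr$config$dx, numeric(1))
  ref <- trajs[[which.min(dxs)]]
  rows <- dplyr::bind_rows(lapply(trajs, convergence_error, ref = ref,
                                  t0 = t0, t1 = t1))
  dplyr::arrange(rows, dplyr::desc(.data$dx_um))
}

#' Volume-normalized acetate consumption flux
#'
#' Total applied acetate uptake (`sum_sites m * |v_ac,uptake|`) divided by
#' the colony volume, in mM/hr; optionally relative to a reference value
#' (e.g. another strain's turnover).
#'
#' @param state A `lattice_state` with applied fluxes.
#' @param normalize_to Optional reference turnover; when given, the ratio is
#'   returned.
#' @return Turnover (mM/hr) or ratio; `NA` sentinel for an empty colony.
#' @export
acetate_turnover <- function(state, normalize_to = NULL) {
  m_tot <- site_mass(state)
  vol_fL <- sum(m_tot > 0) * site_volume(state)  # occupied-site colony volume
  if (vol_fL <= 0) return(NA_real_)
  v <- state$applied$ace_uptake
  if (is.null(v)) return(NA_real_)
  uptake <- pmax(-v, 0)  # magnitudes of consumption only
  turn <- sum(state$biomass$ACETATE_UTILIZER * uptake) / vol_fL
  if (!is.null(normalize_to)) turn / normalize_to else turn
}

#' Correlate two per-strain characteristics
#'
#' Pearson correlation with the two-tailed p-value from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble with `r`, `p_value`, `n`, and `degenerate` (TRUE
#'   when either vector has zero variance, in which case `r` is `NA`).
#' @export
correlate_characteristics <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                          degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), degenerate = FALSE)
}
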