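#' Fit oxygen capacity and maintenance to a strain record
#'
#' Genome-scale models generally do not reproduce measured growth and acetate
#' rates at measured glucose uptakes out of the box; the maximal oxygen uptake
#' and the growth-associated maintenance (GAM) are therefore adjusted to
#' minimize the summed absolute relative error of the FBA-predicted growth and
#' acetate rates against the record, with glucose uptake fixed at the measured
#' values. The aerobic condition determines (`v_o2_max`, `gam_aero`) on a
#' coarse grid followed by local refinement; the anaerobic condition (no
#' oxygen, so `v_o2_max` is inert) determines `gam_anaero` by a one-dimensional
#' search. Quantities whose target is zero contribute their absolute deviation
#' (scaled by 1 mmol/gDCW/hr or 1/hr) instead of a relative error.
#'
#' @param model An [fba_model()] with annotated glucose/oxygen/acetate
#'   exchanges and an ATP-bearing biomass reaction.
#' @param record One-row strain record (see [ecoli_strains()]).
#' @param v_o2_range,gam_range Search intervals for the oxygen capacity and
#'   the maintenance.
#' @param n_coarse Nodes per axis of the coarse grid.
#' @param n_refine Refinement rounds (each shrinks the bracket around the
#'   incumbent and re-grids).
#' @return List of class `fitted_params` with `v_o2_max`, `gam_aero`,
#'   `gam_anaero` and `residual_errors`, a tibble of percentage errors for
#'   aerobic/anaerobic growth and acetate.
#' @export
#' @examples
#' mod <- mini_ecoli_model()
#' rec <- predict_strain_record(mod, "toy", v_glc_aero = 8, v_glc_anaero = 12,
#'                              v_o2_max = 12, gam_aero = 55, gam_anaero = 45)
#' fit_strain_parameters(mod, rec)
fit_strain_parameters <- function(model, record,
                                  v_o2_range = c(5, 40),
                                  gam_range = c(10, 130),
                                  n_coarse = 15, n_refine = 3) {
  validate_strain_record(record)
  check <- fba_predict(model, v_glc = record$v_glc_aero,
                       v_o2 = max(v_o2_range), gam = mean(gam_range))
  if (is.na(check$mu)) {
    stop("model infeasible at the measured aerobic glucose uptake (",
         record$v_glc_aero, " mmol/gDCW/hr)", call. = FALSE)
  }

  rel_err <- function(pred, target) {
    if (is.na(pred)) return(1e6)
    if (target > 0) abs(pred - target) / target else abs(pred - target)
  }
  aero_obj <- function(v_o2, gam) {
    p <- fba_predict(model, record$v_glc_aero, v_o2, gam)
    rel_err(p$mu, record$mu_aero) + rel_err(p$ac, record$v_ac_aero)
  }
  anaero_obj <- function(gam) {
    p <- fba_predict(model, record$v_glc_anaero, 0, gam)
    rel_err(p$mu, record$mu_anaero) + rel_err(p$ac, record$v_ac_anaero)
  }

  grid_min2 <- function(f, xr, yr, n) {
    xs <- seq(xr[1], xr[2], length.out = n)
    ys <- seq(yr[1], yr[2], length.out = n)
    vals <- outer(xs, ys, Vectorize(f))
    k <- arrayInd(which.min(vals), dim(vals))
    list(x = xs[k[1]], y = ys[k[2]], dx = diff(xr) / (n - 1),
         dy = diff(yr) / (n - 1))
  }
  best <- grid_min2(aero_obj, v_o2_range, gam_range, n_coarse)
  for (r in seq_len(n_refine)) {
    xr <- pmax(pmin(c(best$x - best$dx, best$x + best$dx),
                    v_o2_range[2]), v_o2_range[1])
    yr <- pmax(pmin(c(best$y - best$dy, best$y + best$dy),
                    gam_range[2]), gam_range[1])
    best <- grid_min2(aero_obj, xr, yr, n_coarse)
  }
  # local polish: the objective is piecewise linear with kinks, which the
  # shrinking grid can straddle; a derivative-free simplex search finishes it
  polish <- stats::optim(
    c(best$x, best$y),
    function(p) {
      if (p[1] < v_o2_range[1] || p[1] > v_o2_range[2] ||
          p[2] < gam_range[1] || p[2] > gam_range[2]) return(1e6)
      aero_obj(p[1], p[2])
    },
    method = "Nelder-Mead",
    control = list(maxit = 300, reltol = 1e-10))
  v_o2_fit <- polish$par[1]
  gam_aero_fit <- polish$par[2]

  gs <- seq(gam_range[1], gam_range[2], length.out = n_coarse^2)
  vals <- vapply(gs, anaero_obj, numeric(1))
  g0 <- gs[which.min(vals)]
  dg <- diff(gam_range) / (n_coarse^2 - 1)
  for (r in seq_len(n_refine)) {
    gs <- seq(max(gam_range[1], g0 - dg), min(gam_range[2], g0 + dg),
              length.out = n_coarse^2)
    vals <- vapply(gs, anaero_obj, numeric(1))
    g0 <- gs[which.min(vals)]
    dg <- dg * 2 / (n_coarse^2 - 1)
  }
  gam_anaero_fit <- g0

  pa <- fba_predict(model, record$v_glc_aero, v_o2_fit, gam_aero_fit)
  pn <- fba_predict(model, record$v_glc_anaero, 0, gam_anaero_fit)
  pct <- function(pred, target) {
    100 * if (target > 0) abs(pred - target) / target else abs(pred - target)
  }
  residual <- tibble::tibble(
    quantity = c("mu_aero", "ac_aero", "mu_anaero", "ac_anaero"),
    predicted = c(pa$mu, pa$ac, pn$mu, pn$ac),
    target = c(record$mu_aero, record$v_ac_aero,
               record$mu_anaero, record$v_ac_anaero),
    error_pct = c(pct(pa$mu, record$mu_aero), pct(pa$ac, record$v_ac_aero),
                  pct(pn$mu, record$mu_anaero), pct(pn$ac, record$v_ac_anaero))
  )
  structure(
    list(v_o2_max = v_o2_fit, gam_aero = gam_aero_fit,
         gam_anaero = gam_anaero_fit, residual_errors = residual),
    class = "fitted_params"
  )
}

#' @export
print.fitted_params <- function(x, ...) {
  cat("<fitted_params> v_o2_max = ", format(x$v_o2_max),
      ", gam_aero = ", format(x$gam_aero),
      ", gam_anaero = ", format(x$gam_anaero), "\n", sep = "")
  print(x$residual_errors)
  invisible(x)
}

# One FBA evaluation at given glucose uptake, O2 capacity and GAM.
fba_predict <- function(model, v_glc, v_o2, gam) {
  m <- model
  if (!is.na(gam)) m <- set_gam(m, gam)
  m <- set_bound(m, m$exchanges$glucose, lb = -abs(v_glc))
  m <- set_bound(m, m$exchanges$oxygen, lb = -abs(v_o2))
  sol <- fba_solve(m)
  if (sol$status != "optimal") return(list(mu = NA_real_, ac = NA_real_))
  list(mu = sol$objective, ac = unname(sol$fluxes[m$exchanges$acetate]))
}

#' Predict a strain record from a model at given parameters
#'
#' Runs aerobic and anaerobic FBA at the supplied glucose uptakes and returns
#' a strain-record tibble whose growth/acetate entries are the model
#' predictions. Useful for building self-consistent fixtures whose fitted
#' parameters are known exactly.
#'
#' @param model An [fba_model()].
#' @param strain Name for the record.
#' @param v_glc_aero,v_glc_anaero Glucose uptake magnitudes.
#' @param v_o2_max Oxygen capacity.
#' @param gam_aero,gam_anaero Maintenance values.
#' @return One-row strain tibble.
#' @export
predict_strain_record <- function(model, strain, v_glc_aero, v_glc_anaero,
                                  v_o2_max, gam_aero, gam_anaero) {
  pa <- fba_predict(model, v_glc_aero, v_o2_max, gam_aero)
  pn <- fba_predict(model, v_glc_anaero, 0, gam_anaero)
  tibble::tibble(
    strain = strain,
    mu_aero = pa$mu, mu_anaero = pn$mu,
    v_glc_aero = v_glc_aero, v_glc_anaero = v_glc_anaero,
    v_ac_aero = max(pa$ac, 0), v_ac_anaero = max(pn$ac, 0),
    v_o2_max = v_o2_max, gam_aero = gam_aero, gam_anaero = gam_anaero
  )
}

#' Build a flux table by solving one LP per grid node
#'
#' Tabulates FBA optima over `n_carbon` evenly spaced carbon-uptake bounds
#' (glucose for the glucose phenotype, acetate for the acetate phenotype)
#' and `n_o2` oxygen-uptake bounds between zero and the respective maxima.
#' Infeasible or failed nodes are stored as zero growth and zero exchange
#' (dormancy) and counted in the returned table's `params$n_failed`.
#'
#' @param model An [fba_model()].
#' @param phenotype `"GLUCOSE_UTILIZER"` or `"ACETATE_UTILIZER"`.
#' @param params A `fitted_params` (or list with `v_o2_max`, `gam_aero`).
#' @param n_carbon,n_o2 Axis divisions (defaults 50 and 160).
#' @param carbon_max Maximal carbon uptake; defaults to the model's current
#'   glucose-exchange bound magnitude for the glucose phenotype and
#'   `ac_uptake_max` for the acetate phenotype.
#' @param ac_uptake_max Acetate-uptake ceiling of the acetate phenotype.
#' @return A `flux_table`.
#' @export
build_flux_table <- function(model, phenotype, params,
                             n_carbon = 50, n_o2 = 160,
                             carbon_max = NULL, ac_uptake_max = 10) {
  phenotype <- match_phenotype(phenotype)
  m <- model
  if (!is.na(m$atp_met) && !is.null(params$gam_aero)) {
    m <- set_gam(m, params$gam_aero)
  }
  carbon_ex <- if (phenotype == "GLUCOSE_UTILIZER") {
    m$exchanges$glucose
  } else {
    m$exchanges$acetate
  }
  if (is.null(carbon_max)) {
    carbon_max <- if (phenotype == "GLUCOSE_UTILIZER") {
      abs(m$lb[match(m$exchanges$glucose, colnames(m$S))])
    } else {
      ac_uptake_max
    }
  }
  # the non-primary carbon source is not co-consumed
  if (phenotype == "ACETATE_UTILIZER") {
    m <- set_bound(m, m$exchanges$glucose, lb = 0)
  }
  carbon_axis <- seq(0, carbon_max, length.out = n_carbon)
  o2_axis <- seq(0, params$v_o2_max, length.out = n_o2)
  qn <- c("v_bm", "v_glc", "v_ac", "v_o2")
  grids <- stats::setNames(
    rep(list(matrix(0, n_carbon, n_o2)), length(qn)), qn)
  n_failed <- 0L
  for (j in seq_len(n_o2)) {
    mj <- set_bound(m, m$exchanges$oxygen, lb = -o2_axis[j])
    for (i in seq_len(n_carbon)) {
      if (carbon_axis[i] == 0) next  # no substrate, no growth
      mij <- set_bound(mj, carbon_ex, lb = -carbon_axis[i])
      sol <- fba_solve(mij)
      if (sol$status != "optimal" || sol$objective < 0) {
        n_failed <- n_failed + 1L
        next
      }
      snap <- function(x) if (abs(x) < 1e-6) 0 else x  # solver tolerance
      grids$v_bm[i, j] <- snap(max(sol$objective, 0))
      grids$v_glc[i, j] <- snap(unname(sol$fluxes[m$exchanges$glucose]))
      grids$v_ac[i, j] <- snap(unname(sol$fluxes[m$exchanges$acetate]))
      grids$v_o2[i, j] <- snap(unname(sol$fluxes[m$exchanges$oxygen]))
    }
  }
  if (n_failed > 0) {
    message("build_flux_table: ", n_failed,
            " node(s) infeasible; stored as zero growth/exchange")
  }
  new_flux_table(phenotype, m$id, carbon_axis, o2_axis, grids,
                 source = "model",
                 params = list(v_o2_max = params$v_o2_max,
                               gam_aero = params$gam_aero,
                               n_failed = n_failed,
                               ac_uptake_max = ac_uptake_max))
}
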