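#' Assemble a simulation configuration
#'
#' Collects everything one colony simulation needs: substrate geometry,
#' strain parameterization (a packaged strain name or a one-row strain
#' record), lattice resolution, durations, species table, regulation
#' parameters and numerical settings. Flux tables default to the surrogate
#' tables of the strain; model-derived tables can be supplied through
#' `tables`.
#'
#' @param geometry A [geometry_spec()].
#' @param strain Strain name (see [ecoli_strains()]) or a one-row record.
#' @param dx Lattice spacing, um.
#' @param duration Simulated time, hr (0 is allowed: only the initial state
#'   is produced).
#' @param fba_interval Metabolic (dFBA) refresh interval, s; diffusion runs
#'   in stability-limited substeps spanning each interval.
#' @param output_interval Snapshot/metric interval, hr.
#' @param species Species table (see [species_table()]).
#' @param regulation List with `theta_glc`, `theta_ace`, `theta_o2` (mM),
#'   `tau` (s), `reversible`.
#' @param constants [cell_constants()].
#' @param safety Fraction of the diffusion stability limit used for substeps.
#' @param tables Optional named list of `flux_table`s
#'   (`GLUCOSE_UTILIZER`, `ACETATE_UTILIZER`).
#' @param ac_uptake_max,ac_yield,ac_o2_per_ac Acetate-phenotype surrogate
#'   parameters (see [surrogate_fluxes()]).
#' @param clamp_chemicals Test mode: freeze all concentration fields
#'   (no diffusion, no reaction), leaving pure biomass dynamics.
#' @param keep_states Keep full lattice snapshots at every output interval
#'   (otherwise only the scalar series).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(geometry = geometry_spec("FLAT"),
                       strain = "MG1655",
                       dx = 10,
                       duration = 40,
                       fba_interval = 36,
                       output_interval = 1,
                       species = species_table(),
                       regulation = list(theta_glc = 0.01, theta_ace = 0.5,
                                         theta_o2 = 0.01, tau = 1800,
                                         reversible = FALSE),
                       constants = cell_constants(),
                       safety = 0.8,
                       tables = NULL,
                       ac_uptake_max = 10,
                       ac_yield = 0.025,
                       ac_o2_per_ac = 2,
                       clamp_chemicals = FALSE,
                       keep_states = TRUE) {
  record <- if (is.character(strain)) strain_record(strain) else {
    validate_strain_record(strain)
  }
  stopifnot(duration >= 0, fba_interval > 0, output_interval > 0)
  if (duration > 0 && output_interval > duration) {
    stop("output_interval must not exceed duration", call. = FALSE)
  }
  dt_min <- stable_dt(dx, max(species$D_agar, species$D_cell_free), 1)
  if (fba_interval < dt_min) {
    stop("fba_interval (", fba_interval,
         " s) is below the diffusion stability step (", format(dt_min),
         " s); refine in time or coarsen the grid", call. = FALSE)
  }
  defaults <- list(theta_glc = 0.01, theta_ace = 0.5, theta_o2 = 0.01,
                   tau = 1800, reversible = FALSE)
  regulation <- utils::modifyList(defaults, regulation)
  if (is.null(tables)) {
    tables <- list(
      GLUCOSE_UTILIZER = build_surrogate_table(
        record, "GLUCOSE_UTILIZER", ac_uptake_max = ac_uptake_max,
        ac_yield = ac_yield, ac_o2_per_ac = ac_o2_per_ac),
      ACETATE_UTILIZER = build_surrogate_table(
        record, "ACETATE_UTILIZER", ac_uptake_max = ac_uptake_max,
        ac_yield = ac_yield, ac_o2_per_ac = ac_o2_per_ac)
    )
  }
  structure(
    list(geometry = geometry, strain = record, dx = dx, duration = duration,
         fba_interval = fba_interval, output_interval = output_interval,
         species = species, regulation = regulation, constants = constants,
         safety = safety, tables = tables,
         ac_uptake_max = ac_uptake_max, ac_yield = ac_yield,
         ac_o2_per_ac = ac_o2_per_ac,
         clamp_chemicals = clamp_chemicals, keep_states = keep_states),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$strain$strain, " on ", x$geometry$kind,
      ", dx = ", x$dx, " um, ", x$duration, " hr (dFBA every ",
      x$fba_interval, " s)\n", sep = "")
  invisible(x)
}

#' Scaled-down study preset
#'
#' A reduced-domain configuration (0.6 x 0.6 x 0.72 mm with 0.48 mm of agar,
#' 40 um grid) dimensioned so that the diffusion-limited glucose penetration
#' into a packed colony (roughly 150 um with these supply parameters) is well
#' below the 240 um air gap: glucose starvation at the colony top — and with
#' it acetate cross-feeding — can then emerge before the colony interacts
#' with the domain boundary, as in the full-scale system. Used throughout the
#' package's tests and reproduction scripts.
#'
#' @param kind Geometry kind (see [geometry_spec()]).
#' @param strain Strain name or record.
#' @param dx Lattice spacing, um.
#' @param duration Simulated hours.
#' @param ... Further arguments to [geometry_spec()] (e.g. `o`, `radius`) or
#'   [sim_config()].
#' @return A `sim_config`.
#' @export
preset_scaled <- function(kind = "FLAT", strain = "MG1655", dx = 40,
                          duration = 40, ...) {
  dots <- list(...)
  geo_args <- intersect(names(dots), c("h", "w", "o", "radius"))
  geometry <- do.call(geometry_spec, c(
    list(kind = kind, domain = c(600, 600, 720), agar_depth = 480),
    dots[geo_args]))
  cfg_args <- dots[setdiff(names(dots), geo_args)]
  do.call(sim_config, c(
    list(geometry = geometry, strain = strain, dx = dx, duration = duration,
         output_interval = 0.5),
    cfg_args))
}

#' Full-scale preset
#'
#' The laboratory-scale configuration (2 x 2 x 1 mm domain, 0.5 mm agar,
#' 10 um grid, 40 hr). Intended for production runs; several orders of
#' magnitude more expensive than [preset_scaled()].
#'
#' @inheritParams preset_scaled
#' @return A `sim_config`.
#' @export
preset_full <- function(kind = "FLAT", strain = "MG1655", dx = 10,
                        duration = 40, ...) {
  dots <- list(...)
  geo_args <- intersect(names(dots), c("h", "w", "o", "radius"))
  geometry <- do.call(geometry_spec, c(
    list(kind = kind, domain = c(2000, 2000, 1000), agar_depth = 500),
    dots[geo_args]))
  cfg_args <- dots[setdiff(names(dots), geo_args)]
  do.call(sim_config, c(
    list(geometry = geometry, strain = strain, dx = dx, duration = duration),
    cfg_args))
}

# one dFBA coupling step: uptake bounds -> table lookup -> growth ->
# regulation -> pushing. The exchange fluxes are converted to per-site
# reaction rates (mM/hr) and left in state$reaction_rate for co-integration
# with the diffusion substeps (the rates stay frozen over the interval, as in
# dynamic FBA, but are applied continuously so fast species like oxygen reach
# their quasi-steady profiles). `subplan` carries each species' substep
# length, which bounds the per-substep uptake.
engine_step <- function(state, config, subplan = NULL) {
  dt <- config$fba_interval
  if (is.null(subplan)) subplan <- make_subplan(config)
  dt_sub <- vapply(subplan, `[[`, numeric(1), "dt")
  names(dt_sub) <- vapply(subplan, `[[`, character(1), "name")
  V <- site_volume(state)
  m_glu_arr <- state$biomass$GLUCOSE_UTILIZER
  m_ace_arr <- state$biomass$ACETATE_UTILIZER
  idx <- which(m_glu_arr + m_ace_arr > 0)
  if (length(idx) > 0) {
    m_glu <- m_glu_arr[idx]
    m_ace <- m_ace_arr[idx]
    m_tot <- m_glu + m_ace
    sp <- config$species
    Km <- stats::setNames(sp$Km, sp$name)
    tab_g <- config$tables$GLUCOSE_UTILIZER
    tab_a <- config$tables$ACETATE_UTILIZER
    C_glc <- state$conc$glucose[idx]
    C_ace <- state$conc$acetate[idx]
    C_o2 <- state$conc$oxygen[idx]
    if (config$clamp_chemicals) {
      # saturating test mode: availabilities limited only by saturation
      avail_glc <- max(tab_g$carbon_axis) * C_glc / (Km[["glucose"]] + C_glc)
      avail_ace <- max(tab_a$carbon_axis) * C_ace / (Km[["acetate"]] + C_ace)
      o2_g <- max(tab_g$o2_axis) * C_o2 / (Km[["oxygen"]] + C_o2)
      o2_a <- max(tab_a$o2_axis) * C_o2 / (Km[["oxygen"]] + C_o2)
    } else {
      avail_glc <- compute_uptake_bounds(C_glc, m_glu, V, dt_sub[["glucose"]],
                                         max(tab_g$carbon_axis), Km[["glucose"]])
      avail_ace <- compute_uptake_bounds(C_ace, m_ace, V, dt_sub[["acetate"]],
                                         max(tab_a$carbon_axis), Km[["acetate"]])
      o2_g <- compute_uptake_bounds(C_o2, m_tot, V, dt_sub[["oxygen"]],
                                    max(tab_g$o2_axis), Km[["oxygen"]])
      o2_a <- compute_uptake_bounds(C_o2, m_tot, V, dt_sub[["oxygen"]],
                                    max(tab_a$o2_axis), Km[["oxygen"]])
    }
    fx_g <- lookup_fluxes(tab_g, avail_glc, o2_g)
    fx_a <- lookup_fluxes(tab_a, avail_ace, o2_a)
    supp <- state$suppressed[idx]
    if (any(supp)) {
      fx_g$v_bm[supp] <- 0
      fx_a$v_bm[supp] <- 0
      state$suppressed[idx[supp]] <- FALSE
    }
    if (!config$clamp_chemicals) {
      # saturated consumption capacities for the Michaelis-Menten sinks:
      # glucose by transport capacity, oxygen by the demand of the available
      # carbon, acetate by the oxygen-sufficient uptake capacity; acetate
      # secretion is a frozen source from the interval's flux lookup
      o2_demand_g <- -lookup_fluxes(tab_g, avail_glc, max(tab_g$o2_axis))$v_o2
      o2_demand_a <- -lookup_fluxes(tab_a, avail_ace, max(tab_a$o2_axis))$v_o2
      ace_cap <- -lookup_fluxes(tab_a, max(tab_a$carbon_axis), o2_a)$v_ac
      zero <- array(0, state$dims)
      sink_glc <- zero; sink_glc[idx] <- m_glu * max(tab_g$carbon_axis) / V
      sink_o2 <- zero
      sink_o2[idx] <- (m_glu * o2_demand_g + m_ace * o2_demand_a) / V
      sink_ace <- zero; sink_ace[idx] <- m_ace * ace_cap / V
      sec_ace <- zero; sec_ace[idx] <- m_glu * pmax(fx_g$v_ac, 0) / V
      state$reaction_rate <- list(
        glucose = list(secrete = zero, sink_max = sink_glc),
        acetate = list(secrete = sec_ace, sink_max = sink_ace),
        oxygen = list(secrete = zero, sink_max = sink_o2)
      )
    }
    m_glu_arr[idx] <- grow_biomass(m_glu, fx_g$v_bm, dt)
    m_ace_arr[idx] <- grow_biomass(m_ace, fx_a$v_bm, dt)
    state$biomass$GLUCOSE_UTILIZER <- m_glu_arr
    state$biomass$ACETATE_UTILIZER <- m_ace_arr
    applied <- array(0, state$dims)
    applied[idx] <- fx_a$v_ac
    state$applied$ace_uptake <- applied
  }
  reg <- config$regulation
  state <- update_phenotypes(state, dt, reg$theta_glc, reg$theta_ace,
                             reg$theta_o2, reg$tau, reg$reversible)
  state <- push_biomass(state)
  state
}

#' Run one colony simulation
#'
#' Operator-split time stepping: within each metabolic interval the engine
#' (1) converts local concentrations to per-mass uptake availabilities and
#' reads the flux tables, (2) applies exchange fluxes to the chemical fields
#' and grows biomass exponentially at the local rates, (3) updates the
#' phenotype-regulation timers, (4) pushes biomass above the packing cap,
#' then (5) diffuses every species in stability-limited substeps spanning
#' the interval. Snapshots and scalar metrics are captured every
#' `output_interval`. The run is fully deterministic.
#'
#' @param config A [sim_config()].
#' @param quiet Suppress per-hour progress messages.
#' @return Object of class `colony_trajectory` with elements `series`
#'   (tibble of scalar metrics vs time), `states` (lattice snapshots, if
#'   kept), `times_hr` and `config`.
#' @export
run_simulation <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  state <- build_substrate(config$geometry, config$dx, config$species,
                           config$constants)
  state <- seed_colony(state)
  dt <- config$fba_interval
  n_steps <- round(config$duration * 3600 / dt)
  out_every <- max(1L, round(config$output_interval * 3600 / dt))
  subplan <- make_subplan(config)
  snapshot <- function(state) {
    list(time_hr = state$t / 3600,
         series = trajectory_metrics(state, config),
         state = if (config$keep_states) state)
  }
  snaps <- vector("list", floor(n_steps / out_every) + 1L)
  snaps[[1]] <- snapshot(state)
  isnap <- 1L
  for (step in seq_len(n_steps)) {
    state <- engine_step(state, config, subplan)
    if (!config$clamp_chemicals) {
      for (pl in subplan) {
        state <- step_diffusion(state, pl$name, pl$dt, pl$nsub, "dirichlet",
                                reaction = state$reaction_rate[[pl$name]])
      }
    }
    state$t <- state$t + dt
    check <- total_biomass(state) + sum(state$conc$glucose[1])
    if (!is.finite(check)) {
      stop("non-finite state at t = ", format(state$t / 3600, digits = 4),
           " hr", call. = FALSE)
    }
    if (step %% out_every == 0L) {
      isnap <- isnap + 1L
      snaps[[isnap]] <- snapshot(state)
      if (!quiet && (state$t %% 3600 < dt)) {
        message(sprintf("t = %5.1f hr  biomass %.3g fg",
                        state$t / 3600, total_biomass(state)))
      }
    }
  }
  snaps <- snaps[!vapply(snaps, is.null, logical(1))]
  series <- dplyr::bind_rows(lapply(snaps, `[[`, "series"))
  structure(
    list(series = series,
         states = if (config$keep_states) lapply(snaps, `[[`, "state"),
         times_hr = series$time_hr,
         config = config),
    class = "colony_trajectory"
  )
}

# per-species stability-limited substep plan spanning one metabolic interval
make_subplan <- function(config) {
  lapply(seq_len(nrow(config$species)), function(i) {
    sp <- config$species[i, ]
    Dmax <- max(sp$D_agar, sp$D_cell_free)
    lim <- stable_dt(config$dx, Dmax, config$safety)
    nsub <- max(1L, as.integer(ceiling(config$fba_interval / lim)))
    list(name = sp$name, nsub = nsub, dt = config$fba_interval / nsub)
  })
}

# scalar metrics captured at every output time
trajectory_metrics <- function(state, config) {
  rho <- state$consts$rho
  m_glu <- sum(state$biomass$GLUCOSE_UTILIZER)
  m_ace <- sum(state$biomass$ACETATE_UTILIZER)
  m_tot <- m_glu + m_ace
  dims_row <- colony_dimensions(state)
  occ <- which(site_mass(state) > 0, arr.ind = TRUE)
  zmax <- if (nrow(occ) > 0) max(occ[, 3]) * state$dx else NA_real_
  active <- if (m_ace > 0 && !is.null(state$applied$ace_uptake)) {
    sum(state$biomass$ACETATE_UTILIZER[state$applied$ace_uptake < -1e-9]) / m_ace
  } else {
    NA_real_
  }
  turn <- acetate_turnover(state)
  tibble::tibble(
    time_hr = state$t / 3600,
    mass_total_fg = m_tot,
    vol_total_fL = m_tot / rho,
    vol_glu_fL = m_glu / rho,
    vol_ace_fL = m_ace / rho,
    frac_ace = if (m_tot > 0) m_ace / m_tot else NA_real_,
    frac_ace_active = active,
    height_um = dims_row$height_um,
    width_um = dims_row$width_um,
    aspect = dims_row$aspect,
    zmax_um = zmax,
    turnover_mM_hr = turn
  )
}

#' @export
print.colony_trajectory <- function(x, ...) {
  cat("<colony_trajectory> ", x$config$strain$strain, " on ",
      x$config$geometry$kind, ", ", nrow(x$series), " samples to ",
      format(max(x$times_hr), digits = 4), " hr\n", sep = "")
  last <- x$series[nrow(x$series), ]
  cat("  final volume ", format(last$vol_total_fL, digits = 4),
      " fL, acetate-capable fraction ",
      format(100 * last$frac_ace, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Tidy a colony trajectory into a long metric series
#'
#' @param x A `colony_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time_hr`, `metric`, `value`.
#' @export
tidy.colony_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$series, -"time_hr", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a colony trajectory
#'
#' @param x A `colony_trajectory`.
#' @param onset_threshold Acetate-capable fraction defining cross-feeding
#'   onset.
#' @param ... Unused.
#' @return One-row tibble: strain, geometry, final volumes and fractions,
#'   onset time.
#' @export
glance.colony_trajectory <- function(x, onset_threshold = 0.01, ...) {
  last <- x$series[nrow(x$series), ]
  tibble::tibble(
    strain = x$config$strain$strain,
    geometry = x$config$geometry$kind,
    duration_hr = max(x$times_hr),
    final_vol_fL = last$vol_total_fL,
    final_frac_ace = last$frac_ace,
    max_frac_ace = max(x$series$frac_ace, na.rm = TRUE),
    onset_hr = onset_time(
      dplyr::select(x$series, "time_hr", value = "frac_ace"),
      threshold = onset_threshold),
    final_aspect = last$aspect
  )
}

#' Plot the colony volume and acetate-capable fraction over time
#'
#' @param object A `colony_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.colony_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$series, "time_hr", "vol_total_fL", "frac_ace"),
    -"time_hr", names_to = "metric", values_to = "value")
  labs <- c(vol_total_fL = "colony volume (fL)",
            frac_ace = "acetate-capable fraction")
  df$metric <- labs[df$metric]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hr, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (hr)", y = NULL,
                  title = paste(object$config$strain$strain, "on",
                                object$config$geometry$kind))
}
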