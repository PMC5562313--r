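#' Cell volume fraction of a biomass amount
#'
#' `phi = m / (V * rho)` with `rho` the single-cell density (258 fg/fL by
#' default).
#'
#' @param m Biomass, fg.
#' @param V Site volume, fL.
#' @param consts [cell_constants()].
#' @return Volume fraction.
#' @export
#' @examples
#' volume_fraction(258, 1000)  # one cell in a 10-um site: 0.001
volume_fraction <- function(m, V, consts = cell_constants()) {
  stopifnot(all(m >= 0), V > 0)
  m / (V * consts$rho)
}

#' Exponential biomass growth over one step
#'
#' Integrates `dm/dt = v_bm * m` exactly over the step at frozen growth rate:
#' `m * exp(v_bm * dt)`.
#'
#' @param m Biomass, fg.
#' @param v_bm Growth rate, 1/hr.
#' @param dt Step length, s.
#' @return Updated biomass, fg.
#' @export
grow_biomass <- function(m, v_bm, dt) {
  stopifnot(all(m >= 0), all(v_bm >= 0), dt >= 0)
  m * exp(v_bm * dt / 3600)
}

#' Uptake bound from enzyme saturation and supply
#'
#' The applied uptake magnitude of a species is capped by Michaelis-Menten
#' saturation of the table's maximal rate and by the amount present in the
#' site (so a step of length `dt` cannot drive the concentration negative):
#' `|v| = min(v_table_max * C / (Km + C), C * V * 3600 / (m * dt))`.
#' With no cells (`m = 0`) the bound is 0.
#'
#' @param C Concentration, mM.
#' @param m Consuming biomass, fg (gDCW-equivalent).
#' @param V Site volume, fL.
#' @param dt Step length, s.
#' @param v_table_max Maximal uptake magnitude of the flux table,
#'   mmol/gDCW/hr.
#' @param Km Michaelis constant, mM.
#' @return Uptake bound magnitude, mmol/gDCW/hr (vectorized).
#' @export
compute_uptake_bounds <- function(C, m, V, dt, v_table_max, Km) {
  stopifnot(all(C >= -1e-12), all(m >= 0), V > 0, dt > 0)
  C <- pmax(C, 0)
  mm <- v_table_max * C / (Km + C)
  supply <- ifelse(m > 0, C * V * 3600 / (m * dt), 0)
  out <- pmin(mm, supply)
  out[m == 0] <- 0
  out
}

#' Apply metabolic exchange fluxes to the chemical fields
#'
#' The reaction term couples biomass to concentrations as
#' `dC/dt = sum_p m_p v_{C,p} / V`, which with `m` in fg (= 1e-15 gDCW),
#' `v` in mmol/gDCW/hr and `V` in fL (= 1e-15 L) is directly in mM/hr.
#' Uptake (negative `v`) must respect [compute_uptake_bounds()]; a resulting
#' concentration below `-1e-12` indicates a bound violation and is an error.
#'
#' @param state A `lattice_state`.
#' @param site_fluxes Named list (by species name) of 3D arrays holding the
#'   mass-weighted flux `sum_p m_p v_{C,p}` per site, fg * mmol/gDCW/hr.
#' @param dt Step length, s.
#' @return The state with updated concentrations.
#' @export
apply_reaction <- function(state, site_fluxes, dt) {
  V <- site_volume(state)
  dt_hr <- dt / 3600
  for (spn in names(site_fluxes)) {
    dC <- site_fluxes[[spn]] / V * dt_hr
    newC <- state$conc[[spn]] + dC
    if (any(newC < -1e-9)) {
      stop("apply_reaction drove ", spn, " below zero (min ",
           format(min(newC)), " mM): uptake bound violated", call. = FALSE)
    }
    state$conc[[spn]] <- pmax(newC, 0)
  }
  state
}

#' Phenotype regulation: glucose starvation converts to acetate utilization
#'
#' At sites where glucose is below `theta_glc` while acetate exceeds
#' `theta_ace` (and, because the target phenotype catabolizes acetate
#' aerobically, oxygen exceeds `theta_o2`), a dwell timer accrues; anywhere
#' the condition breaks the timer resets to zero. Once a site's timer reaches
#' `tau`, all glucose-utilizer mass there converts to acetate-utilizer mass.
#' Without the oxygen condition the entire anoxic colony interior — which is
#' glucose-starved and acetate-rich but metabolically dormant — would
#' convert; gating induction on aerobiosis confines the transition to the
#' oxygenated acetate-rich shell (set `theta_o2 = 0` to disable). The
#' transition is irreversible unless `reversible = TRUE`, in which case
#' acetate-utilizer mass converts back at sites with glucose above
#' `theta_glc` after the same dwell time (tracked by the same timer logic on
#' the reverse condition).
#'
#' @param state A `lattice_state`.
#' @param dt Step length, s.
#' @param theta_glc Glucose starvation threshold, mM.
#' @param theta_ace Acetate sufficiency threshold, mM.
#' @param theta_o2 Oxygen presence threshold, mM (0 disables the oxygen
#'   condition).
#' @param tau Required dwell time, s.
#' @param reversible Allow the reverse transition (default off).
#' @return The state with updated biomass fields and timers.
#' @export
update_phenotypes <- function(state, dt, theta_glc = 0.01, theta_ace = 0.5,
                              theta_o2 = 0.01, tau = 1800,
                              reversible = FALSE) {
  cellmass <- site_mass(state) > 0
  cond <- cellmass & state$conc$glucose < theta_glc &
    state$conc$acetate > theta_ace
  if (theta_o2 > 0) cond <- cond & state$conc$oxygen > theta_o2
  state$reg_timer <- ifelse(cond, state$reg_timer + dt, 0)
  convert <- cond & state$reg_timer >= tau &
    state$biomass$GLUCOSE_UTILIZER > 0
  if (any(convert)) {
    state$biomass$ACETATE_UTILIZER[convert] <-
      state$biomass$ACETATE_UTILIZER[convert] +
      state$biomass$GLUCOSE_UTILIZER[convert]
    state$biomass$GLUCOSE_UTILIZER[convert] <- 0
  }
  if (reversible) {
    rcond <- cellmass & state$conc$glucose >= theta_glc &
      state$biomass$ACETATE_UTILIZER > 0
    if (is.null(state$rev_timer)) state$rev_timer <- array(0, state$dims)
    state$rev_timer <- ifelse(rcond, state$rev_timer + dt, 0)
    rconv <- rcond & state$rev_timer >= tau
    if (any(rconv)) {
      state$biomass$GLUCOSE_UTILIZER[rconv] <-
        state$biomass$GLUCOSE_UTILIZER[rconv] +
        state$biomass$ACETATE_UTILIZER[rconv]
      state$biomass$ACETATE_UTILIZER[rconv] <- 0
    }
  }
  state
}

#' Isotropic pushing of biomass at the packing cap
#'
#' Sites whose total volume fraction exceeds `phi_max` export their excess
#' mass, split equally among face neighbors that are not agar (phenotype
#' proportions of the exported mass match the donor site). Mass pushed across
#' the domain boundary is removed (absorbing boundary). Sweeps repeat until
#' the largest remaining overflow is below `1e-6 * phi_max` (in mass units)
#' or the sweep cap is reached. A site with no eligible neighbor retains its
#' excess and is flagged so the engine suppresses its growth on the next
#' step.
#'
#' @param state A `lattice_state`.
#' @param consts [cell_constants()] (defaults to the state's).
#' @param max_sweeps Sweep cap; exceeding it aborts with a diagnostic (it
#'   indicates a fully enclosed colony).
#' @return The state with redistributed biomass.
#' @export
push_biomass <- function(state, consts = NULL, max_sweeps = 10000L) {
  if (is.null(consts)) consts <- state$consts
  V <- site_volume(state)
  cap <- consts$phi_max * consts$rho * V            # fg per site
  tol <- 1e-6 * consts$phi_max * consts$rho * V
  m1 <- as.numeric(state$biomass$GLUCOSE_UTILIZER)
  m2 <- as.numeric(state$biomass$ACETATE_UTILIZER)
  cache <- state_cache(state)
  suppressed <- as.logical(state$suppressed)
  sweeps <- push_biomass_cpp(m1, m2, cache$nbtab0,
                             cache$agar,
                             cap, tol, as.integer(max_sweeps), suppressed)
  if (sweeps < 0) {
    stop("push_biomass did not converge in ", max_sweeps,
         " sweeps: colony appears fully enclosed", call. = FALSE)
  }
  state$biomass$GLUCOSE_UTILIZER <- array(m1, state$dims)
  state$biomass$ACETATE_UTILIZER <- array(m2, state$dims)
  state$suppressed <- array(suppressed, state$dims)
  state
}
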