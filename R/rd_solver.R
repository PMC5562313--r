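#' Stability-limited time step for explicit diffusion
#'
#' The forward-time central-space scheme on a cubic lattice is stable for
#' `dt <= dx^2 / (6 D)`; the returned step applies a safety fraction:
#' `dt = safety * dx^2 / (6 * D_max)`.
#'
#' @param dx Lattice spacing, um.
#' @param D_max Largest diffusion coefficient of the species, um^2/s.
#' @param safety Fraction of the stability limit to use, in (0, 1].
#' @return Time step, s.
#' @export
#' @examples
#' stable_dt(10, 1000, safety = 0.5)
stable_dt <- function(dx, D_max, safety = 0.8) {
  stopifnot(dx > 0, D_max > 0, safety > 0, safety <= 1)
  safety * dx^2 / (6 * D_max)
}

#' Cell-crowding attenuation of diffusion
#'
#' Returns the effective diffusivity in a site with total cell volume
#' fraction `phi` under a Maxwell-type obstruction law:
#' `D = D0 * 2 (1 - phi) / (2 + phi)`. Strictly decreasing in `phi`; at the
#' packing cap (`phi` = 0.65) diffusion is attenuated to about 26% of the
#' free value.
#'
#' @param D0 Free diffusivity, um^2/s.
#' @param phi_total Total cell volume fraction, in `[0, phi_max]`.
#' @return Effective diffusivity, um^2/s.
#' @export
effective_diffusion <- function(D0, phi_total) {
  if (any(phi_total < -1e-9 | phi_total > 0.65 + 1e-6)) {
    stop("phi_total outside [0, 0.65]", call. = FALSE)
  }
  phi <- pmin(pmax(phi_total, 0), 1)
  D0 * 2 * (1 - phi) / (2 + phi)
}

# Build the per-species diffusion plan: active site list, neighbor table,
# face conductances, and Dirichlet clamps. `boundary` is "dirichlet" (domain
# boundaries held at the species boundary values, cell-free air clamped for
# gaseous species) or "reflecting" (test harness: closed boundaries, no
# clamps — conserves mass exactly).
diffusion_plan <- function(state, species_name, boundary = c("dirichlet", "reflecting")) {
  boundary <- match.arg(boundary)
  sp <- state$species[state$species$name == species_name, ]
  if (nrow(sp) != 1) stop("unknown species '", species_name, "'", call. = FALSE)
  cache <- state_cache(state)
  n <- prod(state$dims)
  agar <- cache$agar
  cellmass <- as.vector(site_mass(state)) > 0
  phi <- pmin(as.vector(site_mass(state)) /
                (site_volume(state) * state$consts$rho), 1)
  D0 <- ifelse(agar, sp$D_agar, sp$D_cell_free)
  Deff <- D0 * 2 * (1 - phi) / (2 + phi)

  # sites the species may occupy (reads & writes)
  permitted <- agar | cellmass
  if (sp$gaseous) permitted <- rep(TRUE, n)  # gaseous exists in air too

  clamped <- logical(n)
  clamp_val <- numeric(n)
  if (boundary == "dirichlet") {
    bnd <- cache$bnd
    if (sp$gaseous) {
      freeair <- !agar & !cellmass
      clamped <- freeair | bnd
      clamp_val[freeair] <- sp$boundary_value_air
      clamp_val[bnd & agar] <- sp$boundary_value
      clamp_val[bnd & !agar] <- sp$boundary_value_air
    } else {
      clamped <- bnd & permitted
      clamp_val[bnd & agar] <- sp$boundary_value
      clamp_val[bnd & !agar] <- sp$boundary_value_air
    }
  }
  plan <- build_plan_cpp(Deff, permitted, clamped, cache$nbtab0)
  plan$clamped <- clamped
  plan$clamp_val <- clamp_val
  plan$D_max <- max(sp$D_agar, sp$D_cell_free)
  plan
}

#' Advance one species by explicit diffusion
#'
#' Performs `nsub` forward-time central-space substeps of length `dt` with
#' phase-restricted, crowding-attenuated diffusion (face diffusivities are
#' harmonic means of the two adjacent sites' effective diffusivities).
#' With `boundary = "dirichlet"`, domain-boundary sites (and, for gaseous
#' species, all cell-free air sites) are held at the species boundary values;
#' with `boundary = "reflecting"` (test harness) all faces are closed and
#' total mass is conserved.
#'
#' @param state A `lattice_state`.
#' @param species_name Species to advance.
#' @param dt Substep length, s; must satisfy the stability bound
#'   `dx^2 / (6 D_max)`.
#' @param nsub Number of substeps.
#' @param boundary `"dirichlet"` or `"reflecting"`.
#' @param reaction Optional list with fields `secrete` (mM/hr per site,
#'   frozen source) and `sink_max` (mM/hr per site, saturated consumption
#'   rate); consumption is applied every substep as Michaelis-Menten kinetics
#'   `sink_max * C / (Km + C)` so uptake tracks the concentration
#'   continuously and never drives a site negative.
#' @return The state with the species field advanced by `nsub * dt`.
#' @export
step_diffusion <- function(state, species_name, dt, nsub = 1,
                           boundary = "dirichlet", reaction = NULL) {
  plan <- diffusion_plan(state, species_name, boundary)
  if (dt > state$dx^2 / (6 * plan$D_max) + 1e-12) {
    stop("dt = ", dt, " s violates the stability bound ",
         format(state$dx^2 / (6 * plan$D_max)), " s", call. = FALSE)
  }
  C <- as.vector(state$conc[[species_name]])
  C[plan$clamped] <- plan$clamp_val[plan$clamped]
  if (is.null(reaction)) {
    sec <- numeric(0)
    sink <- numeric(0)
    Km <- 1
  } else {
    sec <- as.vector(reaction$secrete) * dt / 3600
    sink <- as.vector(reaction$sink_max) * dt / 3600
    Km <- state$species$Km[state$species$name == species_name]
  }
  out <- diffuse_substeps_cpp(C, plan$active0, plan$nb0, plan$cond,
                              dt / state$dx^2, as.integer(nsub), sec, sink, Km)
  state$conc[[species_name]] <- array(out, state$dims)
  state
}
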