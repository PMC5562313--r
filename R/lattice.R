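#' Single-cell constants and the packing cap
#'
#' The biomass bookkeeping treats cells as incompressible units of mass
#' `m_cell` = 258 fg and volume `V_cell` = 1 fL, so the cell density is
#' `rho = m_cell / V_cell` = 258 fg/fL. Biomass in a lattice site is
#' converted to a volume fraction `phi = m / (V * rho)` and capped at
#' `phi_max` = 0.65, above which mass is pushed into neighboring sites.
#' Biomass is interpreted as dry weight for flux coupling (FBA fluxes are
#' per gDCW).
#'
#' @param m_cell Single-cell mass, fg.
#' @param V_cell Single-cell volume, fL.
#' @param phi_max Maximal total cell volume fraction in a site.
#' @return List of class `cell_constants` (includes derived `rho`, fg/fL).
#' @export
cell_constants <- function(m_cell = 258, V_cell = 1, phi_max = 0.65) {
  stopifnot(m_cell > 0, V_cell > 0, phi_max > 0, phi_max < 1)
  structure(
    list(m_cell = m_cell, V_cell = V_cell, rho = m_cell / V_cell,
         phi_max = phi_max),
    class = "cell_constants"
  )
}

#' Default chemical species table
#'
#' Diffusion coefficients, boundary/initial concentrations and
#' Michaelis-Menten constants for the three tracked species. Aqueous species
#' (glucose, acetate) diffuse only through agar and cell-occupied sites;
#' oxygen is gaseous and is held at its boundary value in cell-free air
#' (well-mixed air approximation). `boundary_value` applies on domain
#' boundary sites lying in agar; `boundary_value_air` on the remaining
#' boundary sites.
#'
#' The default glucose concentration corresponds to 2.5% w/v glucose
#' minimal medium (25 g/L / 180.16 g/mol = 138.8 mM); oxygen to
#' air-saturated water (0.21 mM).
#'
#' @return Tibble with one row per species: `name`, `D_agar`, `D_cell_free`
#'   (um^2/s), `gaseous`, `boundary_value`, `boundary_value_air`, `init_agar`,
#'   `init_air` (mM), `Km` (mM).
#' @export
species_table <- function() {
  tibble::tribble(
    ~name,      ~D_agar, ~D_cell_free, ~gaseous, ~boundary_value, ~boundary_value_air, ~init_agar, ~init_air, ~Km,
    "glucose",  600,     600,          FALSE,    138.8,           0,                   138.8,      0,         0.015,
    "acetate",  1100,    1100,         FALSE,    0,               0,                   0,          0,         0.05,
    "oxygen",   2000,    2000,         TRUE,     0.21,            0.21,                0.21,       0.21,      0.005
  )
}

PHASE_AIR <- 0L
PHASE_AGAR <- 1L

#' Construct an empty lattice state
#'
#' A lattice state holds the per-site phase labels (air/agar), the chemical
#' concentration fields (mM), the per-phenotype biomass fields (fg), the
#' phenotype-regulation dwell timers (s) and the simulation clock. Fields are
#' dense 3D arrays indexed `[x, y, z]` with site spacing `dx` (um); site
#' centers sit at `(i - 1/2) dx`.
#'
#' @param phase Integer 3D array (0 = air, 1 = agar).
#' @param dx Lattice spacing, um.
#' @param species Species table (see [species_table()]).
#' @param consts [cell_constants()].
#' @return Object of class `lattice_state`.
#' @export
lattice_state <- function(phase, dx, species = species_table(),
                          consts = cell_constants()) {
  dims <- dim(phase)
  stopifnot(length(dims) == 3, all(dims >= 3), dx > 0)
  zero <- array(0, dims)
  conc <- lapply(seq_len(nrow(species)), function(i) {
    sp <- species[i, ]
    arr <- zero
    arr[phase == PHASE_AGAR] <- sp$init_agar
    arr[phase == PHASE_AIR] <- sp$init_air
    arr
  })
  names(conc) <- species$name
  st <- structure(
    list(
      dims = dims, dx = dx, phase = phase,
      conc = conc,
      biomass = list(GLUCOSE_UTILIZER = zero, ACETATE_UTILIZER = zero),
      reg_timer = zero,
      suppressed = array(FALSE, dims),
      applied = list(),
      species = species,
      consts = consts,
      seed_index = NULL,
      t = 0
    ),
    class = "lattice_state"
  )
  st$cache <- state_cache(st)
  st
}

#' @export
print.lattice_state <- function(x, ...) {
  cat("<lattice_state> ", paste(x$dims, collapse = " x "), " sites, dx = ",
      x$dx, " um, t = ", format(x$t / 3600, digits = 4), " hr\n", sep = "")
  m <- total_biomass(x)
  cat("  biomass: ", format(m, digits = 6), " fg in ",
      sum(site_mass(x) > 0), " sites; agar sites: ",
      sum(x$phase == PHASE_AGAR), "\n", sep = "")
  invisible(x)
}

site_volume <- function(state) state$dx^3  # fL (1 um^3 = 1 fL)

site_mass <- function(state) {
  state$biomass$GLUCOSE_UTILIZER + state$biomass$ACETATE_UTILIZER
}

total_biomass <- function(state) sum(site_mass(state))

#' Total cell volume fraction field
#'
#' @param state A `lattice_state`.
#' @return 3D array of `sum_i phi_i` per site.
#' @export
phi_total <- function(state) {
  site_mass(state) / (site_volume(state) * state$consts$rho)
}

# 6 x n table of face-neighbor flat indices (1-based), NA_integer_ where the
# face crosses the domain boundary. Order: -x, +x, -y, +y, -z, +z.
neighbor_table <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  idx <- seq_len(n)
  x <- ((idx - 1L) %% nx) + 1L
  y <- (((idx - 1L) %/% nx) %% ny) + 1L
  z <- ((idx - 1L) %/% (nx * ny)) + 1L
  shift <- function(cond, off) ifelse(cond, idx + off, NA_integer_)
  rbind(
    shift(x > 1L, -1L),
    shift(x < nx, +1L),
    shift(y > 1L, -nx),
    shift(y < ny, +nx),
    shift(z > 1L, -nx * ny),
    shift(z < nz, +nx * ny)
  )
}

# static per-geometry tables reused on every solver call: 0-based neighbor
# table (-1 at domain faces), agar mask and boundary mask as flat vectors
state_cache <- function(state) {
  if (!is.null(state$cache)) return(state$cache)
  nb <- neighbor_table(state$dims)
  nb[is.na(nb)] <- 0L
  list(nbtab0 = nb - 1L,
       agar = as.vector(state$phase == PHASE_AGAR),
       bnd = as.vector(boundary_mask(state$dims)))
}

# logical array marking domain-boundary sites
boundary_mask <- function(dims) {
  arr <- array(FALSE, dims)
  arr[c(1, dims[1]), , ] <- TRUE
  arr[, c(1, dims[2]), ] <- TRUE
  arr[, , c(1, dims[3])] <- TRUE
  arr
}
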