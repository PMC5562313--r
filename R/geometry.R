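#' Parametric substrate geometry
#'
#' Describes one of six agar substrate shapes: `FLAT` (plain slab), `WALL`
#' (slab plus a 90-degree agar step whose face sits `o` um from the seed),
#' `PLATEAU` (square agar column of height `h` and width `w` on the slab),
#' `HOLE` (square depression of depth `h` and width `w` in the slab),
#' `CONCAVE` / `CONVEX` (cylinder-section surface of radius `radius`, curved
#' along x only). All lengths in um. The wall block and all raised/lowered
#' features are agar containing the same initial glucose as the base slab.
#'
#' @param kind One of `"FLAT"`, `"WALL"`, `"PLATEAU"`, `"HOLE"`, `"CONCAVE"`,
#'   `"CONVEX"`.
#' @param domain Domain edge lengths `c(Lx, Ly, Lz)`, um.
#' @param agar_depth Thickness of the base agar slab, um.
#' @param h Feature height/depth (wall step, plateau, hole), um.
#' @param w Feature width (square footprint of plateau/hole), um.
#' @param o Seed offset from the wall face (wall only), um.
#' @param radius Cylinder radius (concave/convex), um; the reported curvature
#'   is `kappa = 1000 / radius` per mm.
#' @return Object of class `geometry_spec`.
#' @export
#' @examples
#' geometry_spec("CONCAVE", radius = 2000)$kappa_per_mm  # 0.5
geometry_spec <- function(kind = c("FLAT", "WALL", "PLATEAU", "HOLE",
                                   "CONCAVE", "CONVEX"),
                          domain = c(600, 600, 480), agar_depth = 240,
                          h = 120, w = 240, o = 0, radius = 1000) {
  kind <- match.arg(kind)
  stopifnot(length(domain) == 3, all(domain > 0),
            agar_depth > 0, agar_depth < domain[3])
  if (kind %in% c("PLATEAU", "HOLE", "WALL")) stopifnot(h > 0)
  if (kind %in% c("PLATEAU", "HOLE")) stopifnot(w > 0)
  if (kind == "WALL") stopifnot(o >= 0)
  if (kind %in% c("CONCAVE", "CONVEX")) stopifnot(radius > 0)
  if (kind == "HOLE") stopifnot(h < agar_depth)
  structure(
    list(kind = kind, domain = domain, agar_depth = agar_depth,
         h = h, w = w, o = o, radius = radius,
         kappa_per_mm = if (kind %in% c("CONCAVE", "CONVEX")) 1000 / radius else NA_real_),
    class = "geometry_spec"
  )
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("<geometry_spec> ", x$kind, ", domain ",
      paste(x$domain, collapse = " x "), " um, agar depth ", x$agar_depth,
      " um\n", sep = "")
  invisible(x)
}

# surface height (um) of the agar at lateral position (x, y), site-center
# coordinates; features are centered on the domain except the wall, whose
# face sits at x_center + o (seed at center).
surface_height <- function(spec, x, y) {
  base <- spec$agar_depth
  cx <- spec$domain[1] / 2
  cy <- spec$domain[2] / 2
  switch(spec$kind,
    FLAT = rep(base, length(x)),
    WALL = ifelse(x > cx + spec$o, base + spec$h, base),
    PLATEAU = ifelse(abs(x - cx) <= spec$w / 2 & abs(y - cy) <= spec$w / 2,
                     base + spec$h, base),
    HOLE = ifelse(abs(x - cx) <= spec$w / 2 & abs(y - cy) <= spec$w / 2,
                  base - spec$h, base),
    CONCAVE = {
      # valley: lowest at the center, rising toward the x edges
      sag <- spec$radius - sqrt(pmax(spec$radius^2 - (x - cx)^2, 0))
      base + sag
    },
    CONVEX = {
      # ridge: highest at the center
      bump <- sqrt(pmax(spec$radius^2 - (x - cx)^2, 0)) -
        sqrt(max(spec$radius^2 - cx^2, 0))
      base + pmax(bump, 0)
    }
  )
}

#' Rasterize a substrate geometry onto a lattice
#'
#' Builds the air/agar phase mask by site-center membership (a site is agar
#' when its center lies below the analytic surface), fills agar sites with
#' the species' initial concentrations, and leaves the air above. Every
#' feature must span at least two sites at the requested resolution.
#'
#' @param spec A [geometry_spec()].
#' @param dx Lattice spacing, um; must divide the domain edge lengths.
#' @param species Species table.
#' @param consts [cell_constants()].
#' @return A `lattice_state` with phase mask and initial concentrations, no
#'   biomass.
#' @export
build_substrate <- function(spec, dx, species = species_table(),
                            consts = cell_constants()) {
  stopifnot(inherits(spec, "geometry_spec"), dx > 0)
  dims <- round(spec$domain / dx)
  if (max(abs(dims * dx - spec$domain)) > 1e-6) {
    stop("dx = ", dx, " um does not divide the domain ",
         paste(spec$domain, collapse = " x "), " um", call. = FALSE)
  }
  feat <- switch(spec$kind,
    PLATEAU = c(spec$h, spec$w), HOLE = c(spec$h, spec$w),
    WALL = spec$h, CONCAVE = NULL, CONVEX = NULL, FLAT = NULL)
  if (!is.null(feat) && any(feat < 2 * dx)) {
    stop("feature size (", paste(feat, collapse = ", "),
         " um) not resolvable at dx = ", dx,
         " um (needs >= 2 sites across)", call. = FALSE)
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dx
  zc <- (seq_len(nz) - 0.5) * dx
  xy <- expand.grid(x = xc, y = yc)
  surf <- matrix(surface_height(spec, xy$x, xy$y), nx, ny)
  phase <- array(PHASE_AIR, dims)
  for (k in seq_len(nz)) {
    phase[, , k][zc[k] < surf] <- PHASE_AGAR
  }
  st <- lattice_state(phase, dx, species, consts)
  st$surface <- surf
  st$geometry <- spec
  st
}

#' Seed the colony with a single cell's mass
#'
#' Places glucose-utilizer biomass equal to one cell mass (258 fg by default)
#' at an air site face-adjacent to agar. The default position is the air site
#' directly above the agar surface at the lateral domain center (for the hole
#' geometry this is the hole floor).
#'
#' @param state A `lattice_state` from [build_substrate()].
#' @param position Optional integer site index `c(i, j, k)`; defaults to the
#'   center surface site.
#' @param consts [cell_constants()] (defaults to the state's).
#' @return The state with the seed placed (its index kept in `seed_index`).
#' @export
seed_colony <- function(state, position = NULL, consts = NULL) {
  if (is.null(consts)) consts <- state$consts
  dims <- state$dims
  if (is.null(position)) {
    i <- max(1L, as.integer(ceiling(dims[1] / 2)))
    j <- max(1L, as.integer(ceiling(dims[2] / 2)))
    col <- state$phase[i, j, ]
    k_agar <- which(col == PHASE_AGAR)
    k <- if (length(k_agar) == 0) 1L else max(k_agar) + 1L
    if (k > dims[3]) stop("no air above the agar at the center", call. = FALSE)
    position <- c(i, j, k)
  }
  position <- as.integer(position)
  i <- position[1]; j <- position[2]; k <- position[3]
  if (state$phase[i, j, k] != PHASE_AIR) {
    stop("seed position is not an air site", call. = FALSE)
  }
  nbrs <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
  ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= dims[1] &
    nbrs[, 2] >= 1 & nbrs[, 2] <= dims[2] &
    nbrs[, 3] >= 1 & nbrs[, 3] <= dims[3]
  touches_agar <- any(apply(nbrs[ok, , drop = FALSE], 1, function(p) {
    state$phase[p[1], p[2], p[3]] == PHASE_AGAR
  }))
  if (!touches_agar) {
    stop("seed position is not face-adjacent to agar", call. = FALSE)
  }
  state$biomass$GLUCOSE_UTILIZER[i, j, k] <-
    state$biomass$GLUCOSE_UTILIZER[i, j, k] + consts$m_cell
  state$seed_index <- position
  state
}
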