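#' Load a simulation configuration from YAML
#'
#' Reads a structured key/value configuration and resolves it into a full
#' [sim_config()] with all defaults applied. Unknown keys are rejected with
#' an error naming them. Recognized top-level keys: `geometry` (mapping with
#' `kind` and the [geometry_spec()] parameters), `strain`, `strain_table`
#' (path to a delimited strain table to use instead of the packaged one),
#' `dx`, `duration`, `fba_interval`, `output_interval`, `regulation`
#' (mapping), `safety`, `ac_uptake_max`, `ac_yield`, `ac_o2_per_ac`,
#' `keep_states`.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "strain", "strain_table", "dx", "duration",
             "fba_interval", "output_interval", "regulation", "safety",
             "ac_uptake_max", "ac_yield", "ac_o2_per_ac", "keep_states")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  geo_raw <- raw$geometry %||% list(kind = "FLAT")
  geo_known <- c("kind", "domain", "agar_depth", "h", "w", "o", "radius")
  geo_unknown <- setdiff(names(geo_raw), geo_known)
  if (length(geo_unknown) > 0) {
    stop("unknown geometry key(s): ", paste(geo_unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(geo_raw$domain)) geo_raw$domain <- as.numeric(geo_raw$domain)
  geometry <- do.call(geometry_spec, geo_raw)
  strain <- raw$strain %||% "MG1655"
  if (!is.null(raw$strain_table)) {
    tab <- read_strain_table(raw$strain_table)
    strain <- validate_strain_record(tab[tab$strain == strain, ])
  }
  args <- raw[intersect(names(raw),
                        c("dx", "duration", "fba_interval", "output_interval",
                          "safety", "ac_uptake_max", "ac_yield",
                          "ac_o2_per_ac", "keep_states"))]
  if (!is.null(raw$regulation)) args$regulation <- raw$regulation
  do.call(sim_config, c(list(geometry = geometry, strain = strain), args))
}

#' Write a resolved configuration back to YAML
#'
#' Emits every resolved parameter (including all defaults) so a round trip
#' through [load_config()] reproduces the configuration.
#'
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  geo <- config$geometry
  out <- list(
    geometry = list(kind = geo$kind, domain = geo$domain,
                    agar_depth = geo$agar_depth, h = geo$h, w = geo$w,
                    o = geo$o, radius = geo$radius),
    strain = config$strain$strain,
    dx = config$dx,
    duration = config$duration,
    fba_interval = config$fba_interval,
    output_interval = config$output_interval,
    regulation = config$regulation,
    safety = config$safety,
    ac_uptake_max = config$ac_uptake_max,
    ac_yield = config$ac_yield,
    ac_o2_per_ac = config$ac_o2_per_ac,
    keep_states = config$keep_states
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write run metadata as a sidecar text file
#'
#' Records every resolved parameter, the flux-table provenance
#' (model-derived vs surrogate), units policy, package version and
#' wall-clock information.
#'
#' @param config A `sim_config`.
#' @param path Output path (YAML).
#' @param extra Optional named list appended verbatim.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path, extra = list()) {
  meta <- list(
    package = paste0("colonyfba ", utils::packageVersion("colonyfba")),
    written = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    units = list(length = "um", time = "s (internal) / hr (outputs)",
                 concentration = "mM", mass = "fg",
                 flux = "mmol/gDCW/hr (uptake negative)"),
    flux_tables = lapply(config$tables, function(tb) {
      list(phenotype = tb$phenotype, source = tb$source, strain = tb$strain)
    }),
    strain = as.list(config$strain),
    geometry = config$geometry[c("kind", "domain", "agar_depth", "h", "w",
                                 "o", "radius")],
    dx = config$dx, duration = config$duration,
    fba_interval = config$fba_interval,
    output_interval = config$output_interval,
    regulation = config$regulation,
    constants = config$constants[c("m_cell", "V_cell", "rho", "phi_max")],
    safety = config$safety,
    species = lapply(seq_len(nrow(config$species)), function(i) {
      as.list(config$species[i, ])
    })
  )
  yaml::write_yaml(c(meta, extra), path)
  invisible(path)
}

#' Write lattice fields as a legacy-ASCII VTK structured grid
#'
#' Emits a `STRUCTURED_POINTS` dataset with the phase mask, total volume
#' fraction, per-phenotype volume fractions and every concentration field as
#' point data, readable by ParaView/VisIt.
#'
#' @param state A `lattice_state`.
#' @param path Output path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- state$dims
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("colonyfba state t=%.6g hr", state$t / 3600),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN 0 0 0"),
    sprintf("SPACING %g %g %g", state$dx, state$dx, state$dx),
    sprintf("POINT_DATA %d", prod(d))
  ), con)
  wfield <- function(name, arr) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(arr), digits = 8, trim = TRUE,
                      scientific = TRUE), con)
  }
  wfield("phase", state$phase)
  rhoV <- site_volume(state) * state$consts$rho
  wfield("phi_total", phi_total(state))
  wfield("phi_glucose_utilizer", state$biomass$GLUCOSE_UTILIZER / rhoV)
  wfield("phi_acetate_utilizer", state$biomass$ACETATE_UTILIZER / rhoV)
  for (spn in names(state$conc)) wfield(paste0("conc_", spn), state$conc[[spn]])
  if (!is.null(state$applied$ace_uptake)) {
    wfield("applied_acetate_uptake", state$applied$ace_uptake)
  }
  invisible(path)
}

#' Read scalar fields back from a VTK file written by [write_vtk()]
#'
#' @param path Path to the `.vtk` file.
#' @return Named list of 3D arrays.
#' @export
read_vtk_fields <- function(path) {
  lines <- readLines(path)
  dl <- strsplit(grep("^DIMENSIONS", lines, value = TRUE)[1], " ")[[1]]
  dims <- as.integer(dl[2:4])
  n <- prod(dims)
  starts <- grep("^SCALARS", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(lines[s], " ")[[1]][2]
    vals <- as.numeric(lines[(s + 2):(s + 1 + n)])
    out[[name]] <- array(vals, dims)
  }
  out
}

#' Write the scalar metric series of a trajectory as CSV
#'
#' Column names carry units (`_hr`, `_fL`, `_um`, `_mM_hr`).
#'
#' @param traj A `colony_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(traj, path) {
  readr::write_csv(traj$series, path)
  invisible(path)
}

#' Generate the packaged test fixtures
#'
#' Writes, deterministically and without any download: the five packaged
#' strain records as CSV, a surrogate flux table per strain and phenotype,
#' and three miniature geometry preset configurations sized for sub-minute
#' smoke runs. Every surrogate table is checked against its four anchors
#' (aerobic/anaerobic growth and acetate rates) before writing.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of the written paths.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  strains <- ecoli_strains()
  p <- file.path(out_dir, "strains.csv")
  write_strain_table(strains, p)
  paths <- c(paths, p)
  for (i in seq_len(nrow(strains))) {
    rec <- strains[i, ]
    for (ph in phenotypes()) {
      tb <- build_surrogate_table(rec, ph)
      if (ph == "GLUCOSE_UTILIZER") {
        anch <- surrogate_fluxes(rec, ph,
                                 c(rec$v_glc_aero, rec$v_glc_anaero),
                                 c(rec$v_o2_max, 0))
        stopifnot(
          isTRUE(all.equal(anch$v_bm, c(rec$mu_aero, rec$mu_anaero))),
          isTRUE(all.equal(anch$v_ac, c(rec$v_ac_aero, rec$v_ac_anaero)))
        )
      }
      p <- file.path(out_dir, sprintf("fluxtable_%s_%s.csv", rec$strain,
                                      tolower(ph)))
      write_flux_table(tb, p)
      paths <- c(paths, p)
    }
  }
  presets <- list(
    flat_mini = list(geometry = list(kind = "FLAT", domain = c(400, 400, 320),
                                     agar_depth = 160),
                     strain = "MG1655", dx = 40, duration = 2,
                     output_interval = 0.5),
    wall_mini = list(geometry = list(kind = "WALL", domain = c(400, 400, 320),
                                     agar_depth = 160, h = 80, o = 0),
                     strain = "MG1655", dx = 40, duration = 2,
                     output_interval = 0.5),
    hole_mini = list(geometry = list(kind = "HOLE", domain = c(400, 400, 320),
                                     agar_depth = 160, h = 80, w = 160),
                     strain = "MG1655", dx = 40, duration = 2,
                     output_interval = 0.5)
  )
  for (nm in names(presets)) {
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    yaml::write_yaml(presets[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
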