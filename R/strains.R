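#' Packaged E. coli strain records
#'
#' Chemostat-derived growth characteristics of five closely related
#' *Escherichia coli* strains (B21, Crooks, MG1655, W, W3110) together with
#' the oxygen-uptake and growth-associated-maintenance (GAM) parameters fitted
#' to their genome-scale metabolic models. Rates are magnitudes in
#' mmol/gDCW/hr, growth rates in 1/hr, GAM in mmolATP/gDCW. Sign convention
#' for fluxes elsewhere in the package: uptake negative, secretion positive;
#' the columns here store magnitudes.
#'
#' Columns:
#' * `strain` — strain identifier.
#' * `mu_aero`, `mu_anaero` — optimal growth rate with/without oxygen, 1/hr.
#' * `v_glc_aero`, `v_glc_anaero` — maximal glucose uptake magnitude.
#' * `v_ac_aero`, `v_ac_anaero` — acetate efflux.
#' * `v_o2_max` — fitted maximal oxygen uptake magnitude.
#' * `gam_aero`, `gam_anaero` — fitted growth-associated maintenance.
#' * `err_*_pct` — residual percentage error of the fitted model prediction
#'   against the experimental measurement, for growth and acetate rates.
#'
#' @return A tibble with one row per strain.
#' @export
#' @examples
#' ecoli_strains()
ecoli_strains <- function() {
  tibble::tribble(
    ~strain,   ~mu_aero, ~mu_anaero, ~v_glc_aero, ~v_glc_anaero, ~v_ac_aero, ~v_ac_anaero, ~v_o2_max, ~gam_aero, ~gam_anaero,
    "B21",     0.76,     0.29,       8.0,         11.3,          0.0,        9.17,         15.5,      60.25,     50.45,
    "Crooks",  0.96,     0.77,       12.5,        30.9,          0.0,        25.2,         33.5,      121.45,    59.75,
    "MG1655",  0.84,     0.46,       9.5,         16.7,          3.49,       13.27,        13.9,      60.25,     50.45,
    "W",       0.97,     0.90,       9.9,         27.2,          0.0,        20.53,        17.8,      54.55,     35.65,
    "W3110",   0.61,     0.52,       6.7,         17.5,          3.03,       13.63,        7.5,       36.65,     41.65
  ) |>
    dplyr::mutate(
      err_mu_aero_pct   = c(0, 0, 15.2, 0, 0),
      err_mu_anaero_pct = c(0, 0, 0, 0, 0),
      err_ac_aero_pct   = c(0, 0, 0, 0, 2.7),
      err_ac_anaero_pct = c(3.9, 32, 13.3, 2.6, 28.7)
    )
}

strain_record_cols <- c(
  "strain", "mu_aero", "mu_anaero", "v_glc_aero", "v_glc_anaero",
  "v_ac_aero", "v_ac_anaero", "v_o2_max", "gam_aero", "gam_anaero"
)

#' Validate a strain record
#'
#' Checks the invariants of a one-row strain record: all rates non-negative
#' (magnitudes), anaerobic glucose uptake at least the aerobic one, and
#' aerobic growth at least the anaerobic one.
#'
#' @param record A one-row data frame with the columns of [ecoli_strains()].
#' @return The record, invisibly, after validation.
#' @export
validate_strain_record <- function(record) {
  record <- tibble::as_tibble(record)
  missing <- setdiff(strain_record_cols, names(record))
  if (length(missing) > 0) {
    stop("strain record is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(record) != 1) {
    stop("a strain record is a single row; got ", nrow(record), call. = FALSE)
  }
  num <- dplyr::select(record, -"strain") |> dplyr::select(dplyr::where(is.numeric))
  if (any(!is.finite(unlist(num))) || any(unlist(num) < 0)) {
    stop("strain record rates must be finite, non-negative magnitudes", call. = FALSE)
  }
  if (record$v_glc_anaero < record$v_glc_aero) {
    stop("v_glc_anaero must be >= v_glc_aero", call. = FALSE)
  }
  if (record$mu_aero < record$mu_anaero) {
    stop("mu_aero must be >= mu_anaero", call. = FALSE)
  }
  invisible(record)
}

#' Look up one packaged strain by name
#'
#' @param strain Strain identifier, one of `ecoli_strains()$strain`.
#' @return One-row tibble.
#' @export
strain_record <- function(strain) {
  tab <- ecoli_strains()
  hit <- tab[tab$strain == strain, ]
  if (nrow(hit) == 0) {
    stop("unknown strain '", strain, "'; packaged strains: ",
         paste(tab$strain, collapse = ", "), call. = FALSE)
  }
  validate_strain_record(hit)
  hit
}

#' Read a strain table from delimited text
#'
#' Reads a comma- or tab-delimited table whose header matches the columns of
#' [ecoli_strains()] (the fitted-parameter layout of the chemostat
#' characterization table). Every row is validated.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of strain records.
#' @export
read_strain_table <- function(path) {
  tab <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE)
  for (i in seq_len(nrow(tab))) validate_strain_record(tab[i, ])
  tab
}

#' Write a strain table as CSV
#'
#' @param table Tibble of strain records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
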