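fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "lipochrom")
  if (!nzchar(path)) abort(paste0("bundled fixture not found: ", file))
  path
}

check_compound_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(as.character(ids)))) {
    abort(paste0(what, ": missing compound_id in row(s) ",
                 paste(which(is.na(ids) | !nzchar(as.character(ids))), collapse = ", ")))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0(what, ": duplicated compound_id: ", paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

#' Load the bundled 2-aminothiazol-4(5H)-one study dataset
#'
#' Reads the packaged study tables for the 28 pseudothiohydantoin
#' (2-aminothiazol-4(5H)-one) derivatives: compound annotation, the
#' published retention-line parameters for both chromatographic techniques,
#' seven calculated logP scales per compound, and pkCSM-style ADME
#' descriptors with CYP450 inhibition flags.
#'
#' Sign convention: the source table prints the magnitude of the slope
#' (`-S`) as a positive number; the bundled `fits` table stores the signed
#' slope `S` (negative), so `value = intercept + slope * phi` holds literally
#' and `phi0 = -intercept / slope`.
#'
#' @return A named list of tibbles:
#' \describe{
#'   \item{compounds}{`compound_id`, `series` (amino substituent class),
#'     `r1`, `r2` (C-5 substituents), `spiro` (ring label for spiro-fused
#'     derivatives).}
#'   \item{fits}{one row per compound and technique (28 x 2):
#'     `compound_id`, `technique`, `intercept` (`log kw` / `R_M0`), `slope`
#'     (signed S), `phi0`, `abs_correlation`, all as printed in the source.}
#'   \item{calc_logp}{`compound_id` plus the seven calculator columns
#'     `milogP`, `AlogPs`, `AClogP`, `ALOGP`, `MLOGP`, `XLOGP2`, `XLOGP3`.}
#'   \item{adme}{`compound_id`, `log_s` (log mol/L water solubility),
#'     `caco2_log_papp` (log Papp, 1e-6 cm/s), `hia_pct` (% intestinal
#'     absorption), `vdss_log` (log L/kg), `bbb_log_bb`, `fu` (unbound
#'     fraction), logical `cyp2d6` ... `cyp2c9` inhibition flags, and
#'     `cl_tot` (log mL/min/kg total clearance).}
#' }
#' @examples
#' ds <- load_fixture_dataset()
#' nrow(ds$compounds) # 28
#' @export
load_fixture_dataset <- function() {
  compounds <- readr::read_csv(
    fixture_path("compounds.csv"),
    col_types = readr::cols(
      compound_id = readr::col_character(), series = readr::col_character(),
      r1 = readr::col_character(), r2 = readr::col_character(),
      spiro = readr::col_character()
    )
  )
  check_compound_ids(compounds$compound_id, "compounds.csv")
  valid_series <- c("isopropylamino", "tert-butylamino", "adamantylamino")
  if (!all(compounds$series %in% valid_series)) {
    abort("compounds.csv: unknown substituent series")
  }

  fits <- readr::read_csv(
    fixture_path("fits_table1.csv"),
    col_types = readr::cols(
      compound_id = readr::col_character(), technique = readr::col_character(),
      .default = readr::col_double()
    )
  )
  for (tech in TECHNIQUES) {
    check_compound_ids(fits$compound_id[fits$technique == tech],
                       paste0("fits_table1.csv (", tech, ")"))
  }
  if (!all(fits$technique %in% TECHNIQUES)) abort("fits_table1.csv: unknown technique")
  if (any(fits$slope >= 0)) abort("fits_table1.csv: slopes must be negative (signed S)")

  calc_logp <- readr::read_csv(
    fixture_path("calc_logp_table2.csv"),
    col_types = readr::cols(
      compound_id = readr::col_character(), .default = readr::col_double()
    )
  )
  check_compound_ids(calc_logp$compound_id, "calc_logp_table2.csv")
  missing_calc <- setdiff(CALCULATORS, names(calc_logp))
  if (length(missing_calc) > 0) {
    abort(paste0("calc_logp_table2.csv: missing calculator column(s): ",
                 paste(missing_calc, collapse = ", ")))
  }

  adme3 <- readr::read_csv(
    fixture_path("adme_table3.csv"),
    col_types = readr::cols(
      compound_id = readr::col_character(), .default = readr::col_double()
    )
  )
  check_compound_ids(adme3$compound_id, "adme_table3.csv")
  cyp4 <- readr::read_csv(
    fixture_path("cyp_table4.csv"),
    col_types = readr::cols(
      compound_id = readr::col_character(), cl_tot = readr::col_double(),
      .default = readr::col_character()
    )
  )
  check_compound_ids(cyp4$compound_id, "cyp_table4.csv")
  cyp_cols <- tolower(CYP_ISOFORMS)
  cyp4 <- mutate(cyp4, across(all_of(cyp_cols), function(x) {
    if (!all(x %in% c("Yes", "No"))) abort("cyp_table4.csv: inhibition flags must be Yes/No")
    x == "Yes"
  }))
  adme <- left_join(adme3, cyp4, by = "compound_id")
  if (any(adme$fu < 0 | adme$fu > 1)) abort("adme_table3.csv: fu outside [0, 1]")
  if (any(adme$hia_pct < 0 | adme$hia_pct > 100)) {
    abort("adme_table3.csv: hia_pct outside [0, 100]")
  }

  n <- nrow(compounds)
  if (nrow(fits) != 2L * n || nrow(calc_logp) != n || nrow(adme) != n) {
    abort("fixture tables disagree on the compound set")
  }

  list(compounds = compounds, fits = fits, calc_logp = calc_logp, adme = adme)
}

#' Check printed phi0 values against the extrapolation identity
#'
#' For each stored fit, recomputes `phi0 = -intercept / slope` and reports
#' the absolute deviation from the stored `phi0`. In the bundled dataset the
#' stored values are the source table's printed, 3-decimal numbers while the
#' intercept and slope are printed at 2-3 decimals, so deviations up to a few
#' thousandths arise where the original authors extrapolated from unrounded
#' regression parameters. Use `tol` to flag rows whose deviation exceeds
#' what printed-precision rounding alone can explain.
#'
#' @param fits A fits tibble as returned by `load_fixture_dataset()$fits`
#'   (columns `compound_id`, `technique`, `intercept`, `slope`, `phi0`).
#' @param tol Flagging threshold on the absolute deviation (default 0.0005,
#'   i.e. agreement to the printed 3 decimals).
#' @return The input with `phi0_recomputed`, `abs_dev`, and logical
#'   `consistent` (`abs_dev <= tol`) columns appended, sorted by decreasing
#'   deviation.
#' @export
phi0_consistency <- function(fits, tol = 0.0005) {
  stopifnot(all(c("intercept", "slope", "phi0") %in% names(fits)))
  fits %>%
    mutate(
      phi0_recomputed = extrapolate_phi0(.data$intercept, .data$slope),
      abs_dev = abs(.data$phi0_recomputed - .data$phi0),
      consistent = .data$abs_dev <= tol
    ) %>%
    arrange(dplyr::desc(.data$abs_dev))
}
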