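#' R_M transform of a TLC retardation factor
#'
#' `R_M = log10((1 - R_F) / R_F)`, the linearizing transform that makes
#' thin-layer retention comparable to the HPLC log k scale. Strictly
#' decreasing in `R_F`, antisymmetric about `R_F = 0.5`, and undefined at the
#' plate boundaries.
#'
#' @param r_f Retardation factor(s), strictly inside (0, 1). Out-of-range
#'   plate readings are an error, never silently clipped: clipping would bias
#'   the extrapolated `R_M0`.
#' @return Numeric vector of R_M values.
#' @examples
#' rm_from_rf(0.5) # 0
#' rm_from_rf(0.1) # log10(9)
#' @export
rm_from_rf <- function(r_f) {
  stopifnot(is.numeric(r_f))
  if (any(!is.finite(r_f) | r_f <= 0 | r_f >= 1)) {
    abort("invalid input: R_F must lie strictly in (0, 1)")
  }
  log10((1 - r_f) / r_f)
}

#' Inverse R_M transform
#'
#' Recovers the retardation factor from an R_M value,
#' `R_F = 1 / (1 + 10^R_M)`; used by the plate simulator.
#'
#' @param rm R_M value(s).
#' @return Retardation factor(s) in (0, 1).
#' @export
rf_from_rm <- function(rm) {
  stopifnot(is.numeric(rm))
  1 / (1 + 10^rm)
}

#' Build an R_M series from replicate TLC runs
#'
#' Collapses replicate plate readings to one point per modifier fraction:
#' retardation factors are averaged across replicates at each `phi` before
#' the R_M transform.
#'
#' @param runs A data frame of TLC runs with columns `compound_id`, `phi`,
#'   `r_f` and optionally `replicate`. Several compounds may be present.
#' @param min_points Minimum number of distinct `phi` levels per compound
#'   (default 3). The reference design uses five methanol-water phases
#'   (`phi` 0.50-0.70 in steps of 0.05), but any grid of at least
#'   `min_points` levels is accepted.
#' @return A tibble with columns `compound_id`, `technique` (`"RP-TLC"`),
#'   `phi`, `value` (R_M), sorted by compound and ascending `phi`.
#' @export
build_rm_series <- function(runs, min_points = 3L) {
  needed <- c("compound_id", "phi", "r_f")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols) > 0) {
    abort(paste0("runs is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check_phi(runs$phi, "TLC")
  if (any(!is.finite(runs$r_f) | runs$r_f <= 0 | runs$r_f >= 1)) {
    abort("invalid input: R_F must lie strictly in (0, 1)")
  }
  out <- runs %>%
    group_by(.data$compound_id, .data$phi) %>%
    summarise(r_f = mean(.data$r_f), .groups = "drop") %>%
    mutate(technique = "RP-TLC", value = rm_from_rf(.data$r_f)) %>%
    select("compound_id", "technique", "phi", "value") %>%
    arrange(.data$compound_id, .data$phi)
  n_levels <- out %>% count(.data$compound_id)
  low <- n_levels$compound_id[n_levels$n < min_points]
  if (length(low) > 0) {
    abort(paste0(
      "insufficient gradient: fewer than ", min_points,
      " distinct phi levels for compound(s) ", paste(low, collapse = ", ")
    ))
  }
  out
}

#' Fit the R_M line of one compound (RP-TLC)
#'
#' Identical regression contract to [fit_retention_line()]; the intercept is
#' interpreted as the TLC lipophilicity index `R_M0` and
#' `phi0 = -R_M0 / slope`.
#'
#' @inheritParams fit_retention_line
#' @return A `lipo_fit` object with `technique = "RP-TLC"`.
#' @export
fit_rm_line <- function(series, min_points = 3L) {
  check_single_compound(series)
  fit_line_core(series, technique = "RP-TLC", min_points = min_points)
}
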