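#' Retention factor from retention and dead time
#'
#' Computes the dimensionless retention factor `k = t_r / t_m - 1` of an
#' analyte relative to an unretained marker (uracil in the reference assay).
#'
#' @param t_r Retention time in minutes.
#' @param t_m Dead time (column hold-up time) in minutes; must be positive.
#' @return Numeric vector of retention factors, strictly positive. Runs with
#'   `t_r <= t_m` are rejected because log k is undefined downstream.
#' @examples
#' retention_factor(10, 2) # 4
#' @export
retention_factor <- function(t_r, t_m) {
  stopifnot(is.numeric(t_r), is.numeric(t_m))
  if (any(!is.finite(t_m)) || any(t_m <= 0)) {
    abort("invalid input: dead time t_m must be positive and finite")
  }
  if (any(!is.finite(t_r)) || any(t_r <= t_m)) {
    abort("invalid input: retention time t_r must exceed the dead time t_m (k > 0)")
  }
  t_r / t_m - 1
}

check_phi <- function(phi, where = "runs") {
  bad <- which(!is.finite(phi) | phi <= 0 | phi >= 1)
  if (length(bad) > 0) {
    abort(paste0(
      "invalid input: phi must lie strictly in (0, 1); offending ", where,
      " row(s): ", paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(phi)
}

#' Build a log k series from replicate HPLC runs
#'
#' Collapses replicate injections to one point per modifier fraction:
#' retention and dead times are averaged across replicates at each `phi`
#' before the retention-factor transform, and the series value is
#' `log10(k)`.
#'
#' @param runs A data frame of HPLC runs with columns `compound_id`, `phi`,
#'   `t_r_min`, `t_m_min` and optionally `replicate`. Several compounds may
#'   be present; each is reduced separately.
#' @param min_points Minimum number of distinct `phi` levels per compound
#'   (default 3).
#' @return A tibble with columns `compound_id`, `technique` (`"RP-HPLC"`),
#'   `phi`, `value` (log10 k), sorted by compound and ascending `phi`.
#' @examples
#' runs <- tibble::tibble(
#'   compound_id = "1", phi = rep(c(0.6, 0.7, 0.8), each = 2),
#'   t_r_min = c(10, 10, 6, 6, 4, 4), t_m_min = 2
#' )
#' build_log_k_series(runs)
#' @export
build_log_k_series <- function(runs, min_points = 3L) {
  needed <- c("compound_id", "phi", "t_r_min", "t_m_min")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols) > 0) {
    abort(paste0("runs is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check_phi(runs$phi, "HPLC")
  if (any(runs$t_m_min <= 0)) abort("invalid input: t_m_min must be positive")
  if (any(runs$t_r_min <= runs$t_m_min)) {
    abort("invalid input: t_r_min must exceed t_m_min in every run")
  }
  out <- runs %>%
    group_by(.data$compound_id, .data$phi) %>%
    summarise(
      t_r_min = mean(.data$t_r_min),
      t_m_min = mean(.data$t_m_min),
      .groups = "drop"
    ) %>%
    mutate(
      technique = "RP-HPLC",
      value = log10(retention_factor(.data$t_r_min, .data$t_m_min))
    ) %>%
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
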