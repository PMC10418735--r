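check_calc_values <- function(values) {
  missing_calc <- setdiff(CALCULATORS, names(values))
  if (length(missing_calc) > 0) {
    abort(paste0("invalid input: missing calculator value(s): ",
                 paste(missing_calc, collapse = ", ")))
  }
  values <- values[CALCULATORS]
  bad <- CALCULATORS[!is.finite(unlist(values))]
  if (length(bad) > 0) {
    abort(paste0("invalid input: non-finite value for calculator(s): ",
                 paste(bad, collapse = ", ")))
  }
  unlist(values)
}

#' Calculators closest to an experimental lipophilicity value
#'
#' Finds which of the seven logP calculators comes nearest (smallest
#' absolute difference) to an experimentally determined index (`log kw` or
#' `R_M0`). All calculators attaining the minimum are returned: the printed
#' scales carry two decimals and exact ties do occur, so a single-winner
#' answer would need an arbitrary tie-break.
#'
#' @param experimental A single experimental lipophilicity value.
#' @param values Named numeric vector (or one-row data frame / list) holding
#'   the seven calculator values `milogP`, `AlogPs`, `AClogP`, `ALOGP`,
#'   `MLOGP`, `XLOGP2`, `XLOGP3`.
#' @return Character vector of calculator names (never empty; usually
#'   length 1).
#' @examples
#' closest_calculators(3.22, c(
#'   milogP = 2.78, AlogPs = 2.82, AClogP = 2.88, ALOGP = 3.80,
#'   MLOGP = 3.13, XLOGP2 = 2.82, XLOGP3 = 3.33
#' )) # "MLOGP"
#' @export
closest_calculators <- function(experimental, values) {
  stopifnot(is.numeric(experimental), length(experimental) == 1, is.finite(experimental))
  if (is.data.frame(values)) values <- as.list(values)
  v <- check_calc_values(values)
  d <- abs(experimental - v)
  names(v)[d == min(d)]
}

check_same_compounds <- function(a, b, what_a, what_b) {
  ids_a <- sort(as.character(a))
  ids_b <- sort(as.character(b))
  if (!identical(ids_a, ids_b)) {
    abort(paste0("invalid input: compound sets of ", what_a, " and ", what_b,
                 " differ"))
  }
  invisible(NULL)
}

#' Per-compound concordance table of experimental vs calculated logP
#'
#' Long-format comparison of one experimental lipophilicity column against
#' the seven calculated logP scales, with per-compound tie sets of closest
#' calculators.
#'
#' @param experimental A data frame with columns `compound_id` and `value`
#'   (the experimental index, e.g. the `log kw` column of the fits table).
#' @param calc_logp A data frame with `compound_id` and the seven calculator
#'   columns.
#' @return A tibble with one row per compound and calculator:
#'   `compound_id`, `calculator`, `calc_value`, `experimental`, `abs_diff`,
#'   and logical `closest` (member of that compound's tie set).
#' @export
concordance_table <- function(experimental, calc_logp) {
  stopifnot(all(c("compound_id", "value") %in% names(experimental)))
  check_same_compounds(experimental$compound_id, calc_logp$compound_id,
                       "experimental", "calc_logp")
  missing_calc <- setdiff(CALCULATORS, names(calc_logp))
  if (length(missing_calc) > 0) {
    abort(paste0("invalid input: missing calculator column(s): ",
                 paste(missing_calc, collapse = ", ")))
  }
  calc_logp %>%
    mutate(compound_id = as.character(.data$compound_id)) %>%
    tidyr::pivot_longer(all_of(CALCULATORS),
                        names_to = "calculator", values_to = "calc_value") %>%
    left_join(
      experimental %>%
        mutate(compound_id = as.character(.data$compound_id)) %>%
        select("compound_id", experimental = "value"),
      by = "compound_id"
    ) %>%
    mutate(abs_diff = abs(.data$experimental - .data$calc_value)) %>%
    group_by(.data$compound_id) %>%
    mutate(closest = .data$abs_diff == min(.data$abs_diff)) %>%
    ungroup() %>%
    select("compound_id", "calculator", "calc_value", "experimental",
           "abs_diff", "closest")
}

#' Count compounds for which each calculator is closest
#'
#' Counts, per logP calculator, how many compounds have that calculator in
#' their closest-tie set. Ties are credited to every member, so the counts
#' can sum to more than the number of compounds.
#'
#' @inheritParams concordance_table
#' @return A tibble `calculator`, `n_closest`, sorted by decreasing count,
#'   including zero-count calculators.
#' @export
concordance_counts <- function(experimental, calc_logp) {
  tab <- concordance_table(experimental, calc_logp)
  tab %>%
    filter(.data$closest) %>%
    count(.data$calculator, name = "n_closest") %>%
    tidyr::complete(calculator = CALCULATORS,
                    fill = list(n_closest = 0L)) %>%
    arrange(dplyr::desc(.data$n_closest), .data$calculator)
}

#' Lipinski lipophilicity criterion
#'
#' The lipophilicity arm of Lipinski's rule of five for oral druglikeness:
#' logP (here, an experimental chromatographic surrogate) at most 5.
#'
#' @param value Numeric vector of logP-scale values.
#' @param threshold Pass threshold (default 5).
#' @return Logical vector, `TRUE` where `value <= threshold`.
#' @examples
#' lipinski_lipophilicity_flag(c(1.35, 5.63)) # TRUE FALSE
#' @export
lipinski_lipophilicity_flag <- function(value, threshold = 5) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  value <= threshold
}

#' Range of a lipophilicity column
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble with columns `min` and `max`.
#' @export
summarize_range <- function(values) {
  if (length(values) == 0) abort("invalid input: empty value set")
  stopifnot(is.numeric(values), all(is.finite(values)))
  tibble(min = min(values), max = max(values))
}

#' Paired comparison of the two experimental lipophilicity indices
#'
#' Joins the per-compound `log kw` (RP-HPLC) and `R_M0` (RP-TLC) columns and
#' reports their paired differences. In the reference dataset the HPLC index
#' exceeds the TLC index for every compound.
#'
#' @param hplc A data frame `compound_id`, `value` with the `log kw` column.
#' @param tlc A data frame `compound_id`, `value` with the `R_M0` column.
#' @return A tibble `compound_id`, `log_kw`, `rm0`,
#'   `difference` (`log_kw - rm0`), with the number of strictly positive
#'   differences attached as attribute `n_hplc_higher`.
#' @export
paired_difference_report <- function(hplc, tlc) {
  stopifnot(all(c("compound_id", "value") %in% names(hplc)),
            all(c("compound_id", "value") %in% names(tlc)))
  check_same_compounds(hplc$compound_id, tlc$compound_id, "hplc", "tlc")
  out <- hplc %>%
    mutate(compound_id = as.character(.data$compound_id)) %>%
    select("compound_id", log_kw = "value") %>%
    left_join(
      tlc %>%
        mutate(compound_id = as.character(.data$compound_id)) %>%
        select("compound_id", rm0 = "value"),
      by = "compound_id"
    ) %>%
    mutate(difference = .data$log_kw - .data$rm0)
  attr(out, "n_hplc_higher") <- sum(out$difference > 0)
  out
}
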