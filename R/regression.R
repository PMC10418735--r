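#' Extrapolate the isohydric modifier fraction phi0
#'
#' Given the intercept and slope of a retention line (log k or R_M against the
#' organic-modifier volume fraction), returns the modifier fraction at which
#' the fitted retention measure equals zero, `phi0 = -intercept / slope`.
#'
#' @param intercept Numeric vector of line intercepts (`log kw` for RP-HPLC,
#'   `R_M0` for RP-TLC).
#' @param slope Numeric vector of line slopes (per unit volume fraction;
#'   negative for typical reversed-phase retention).
#' @return Numeric vector of volume fractions. Elements with a zero slope are
#'   `NA` (phi0 is undefined on a flat line) and raise a warning.
#' @examples
#' extrapolate_phi0(1.35, -2.975) # 0.4538
#' @export
extrapolate_phi0 <- function(intercept, slope) {
  stopifnot(is.numeric(intercept), is.numeric(slope))
  out <- -intercept / slope
  zero <- !is.na(slope) & slope == 0
  if (any(zero)) {
    warning("slope is zero for ", sum(zero), " fit(s); phi0 is undefined there")
    out[zero] <- NA_real_
  }
  out
}

fit_line_core <- function(series, technique, min_points = 3L) {
  needed <- c("compound_id", "phi", "value")
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0) {
    abort(paste0("series is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(series$phi)) || !all(is.finite(series$value))) {
    abort("series contains non-finite phi or value")
  }
  n_phi <- length(unique(series$phi))
  if (n_phi < min_points) {
    abort(paste0(
      "insufficient gradient: ", n_phi, " distinct phi level(s), need at least ",
      min_points
    ))
  }
  if (sd(series$phi) == 0) {
    abort("degenerate design: zero variance in phi")
  }

  fit <- lm(value ~ phi, data = series)
  slope <- unname(coef(fit)[["phi"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  if (sd(series$value) == 0) {
    # constant response: the true slope is exactly zero, not the ~1e-16 the
    # QR decomposition returns, and phi0 is undefined
    slope <- 0
    intercept <- series$value[[1]]
  }
  # |r|: the retention literature reports the correlation magnitude next to a
  # negative slope, so the sign carries no information here.
  r <- suppressWarnings(cor(series$phi, series$value))
  abs_r <- if (is.na(r)) NA_real_ else abs(r)
  phi0 <- if (slope == 0) NA_real_ else -intercept / slope
  n <- nrow(series)
  res_sd <- if (n > 2) sqrt(sum(residuals(fit)^2) / (n - 2)) else NA_real_

  structure(
    list(
      compound_id = as.character(series$compound_id[[1]]),
      technique = technique,
      intercept = intercept,
      slope = slope,
      abs_correlation = abs_r,
      phi0 = phi0,
      n_points = n,
      residual_sd = res_sd,
      model = fit,
      data = as_tibble(series)
    ),
    class = "lipo_fit"
  )
}

check_single_compound <- function(series) {
  ids <- unique(as.character(series$compound_id))
  if (length(ids) != 1) {
    abort(paste0(
      "series mixes ", length(ids),
      " compounds; fit one compound at a time or use fit_lipophilicity()"
    ))
  }
  invisible(ids)
}

#' Fit the retention line of one compound (RP-HPLC)
#'
#' Ordinary least-squares fit of `value = intercept + slope * phi` to a
#' single-compound log k series, the linear isocratic retention model of
#' Soczewinski and Wachtmeister. The intercept is the lipophilicity index
#' `log kw` (retention extrapolated to pure water) and `phi0 = -intercept/slope`
#' is the modifier fraction at which log k = 0.
#'
#' @param series A data frame with columns `compound_id`, `phi`, `value`
#'   (log10 retention factor), as produced by [build_log_k_series()].
#' @param min_points Minimum number of distinct `phi` levels required
#'   (default 3; a correlation coefficient is meaningless below that).
#' @return A `lipo_fit` object; see [glance.lipo_fit()] for the one-row
#'   summary and [tidy.lipo_fit()] for coefficient-level output.
#' @seealso [fit_rm_line()] for the RP-TLC analogue, [fit_lipophilicity()]
#'   for fitting many compounds at once.
#' @examples
#' series <- tibble::tibble(
#'   compound_id = "1", phi = seq(0.55, 0.95, 0.05),
#'   value = 1.35 - 2.975 * seq(0.55, 0.95, 0.05)
#' )
#' glance(fit_retention_line(series))
#' @export
fit_retention_line <- function(series, min_points = 3L) {
  check_single_compound(series)
  fit_line_core(series, technique = "RP-HPLC", min_points = min_points)
}

#' Fit lipophilicity lines for many compounds
#'
#' Maps [fit_retention_line()] / [fit_rm_line()] over every compound in a
#' retention series table and binds the one-row summaries.
#'
#' @param series A data frame with columns `compound_id`, `phi`, `value`, and
#'   optionally `technique` (otherwise supplied via the `technique` argument).
#' @param technique `"RP-HPLC"` or `"RP-TLC"`; ignored when the series carries
#'   its own `technique` column.
#' @param min_points Passed to the per-compound fit.
#' @return A tibble with one row per compound: `compound_id`, `technique`,
#'   `intercept`, `slope`, `abs_correlation`, `phi0`, `n_points`,
#'   `residual_sd`.
#' @export
fit_lipophilicity <- function(series, technique = NULL, min_points = 3L) {
  if (is.null(technique)) {
    if (!"technique" %in% names(series)) {
      abort("supply `technique` or include a technique column in `series`")
    }
  } else {
    technique <- arg_match0(technique, TECHNIQUES)
    series$technique <- technique
  }
  series %>%
    group_by(.data$compound_id, .data$technique) %>%
    dplyr::group_map(function(df, key) {
      fit <- fit_line_core(
        mutate(df, compound_id = key$compound_id),
        technique = key$technique, min_points = min_points
      )
      glance(fit)
    }) %>%
    bind_rows() %>%
    arrange(.data$technique, .data$compound_id)
}

#' @export
print.lipo_fit <- function(x, ...) {
  cat(sprintf(
    "<lipo_fit> %s, compound %s\n  %s = %.4f %+.4f * phi  (n = %d, |r| = %s)\n  phi0 = %s\n",
    x$technique, x$compound_id,
    if (x$technique == "RP-HPLC") "log k" else "R_M",
    x$intercept, x$slope, x$n_points,
    ifelse(is.na(x$abs_correlation), "NA", sprintf("%.4f", x$abs_correlation)),
    ifelse(is.na(x$phi0), "undefined (zero slope)", sprintf("%.3f", x$phi0))
  ))
  invisible(x)
}

#' Tidy a retention-line fit
#'
#' @param x A `lipo_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (`(Intercept)`, `phi`) and
#'   columns `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.lipo_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
}

#' One-row summary of a retention-line fit
#'
#' @param x A `lipo_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `compound_id`, `technique`, `intercept`
#'   (`log kw` or `R_M0`), `slope`, `abs_correlation`, `phi0`, `n_points`,
#'   `residual_sd`.
#' @exportS3Method generics::glance
glance.lipo_fit <- function(x, ...) {
  tibble(
    compound_id = x$compound_id,
    technique = x$technique,
    intercept = x$intercept,
    slope = x$slope,
    abs_correlation = x$abs_correlation,
    phi0 = x$phi0,
    n_points = x$n_points,
    residual_sd = x$residual_sd
  )
}

#' Per-point fitted values and residuals of a retention-line fit
#'
#' @param x A `lipo_fit` object.
#' @param ... Unused.
#' @return The input series with `.fitted` and `.resid` columns appended.
#' @exportS3Method generics::augment
augment.lipo_fit <- function(x, ...) {
  mutate(
    x$data,
    .fitted = x$intercept + x$slope * .data$phi,
    .resid = .data$value - .data$.fitted
  )
}
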