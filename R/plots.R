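#' Plot a fitted retention line
#'
#' Scatter of the (phi, log k or R_M) points with the fitted
#' extrapolation line, annotated with the intercept and phi0.
#'
#' @param object A `lipo_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lipo_fit <- function(object, ...) {
  lab_y <- if (object$technique == "RP-HPLC") "log k" else expression(R[M])
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$phi, y = .data$value)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(Phi ~ "(modifier volume fraction)"), y = lab_y,
      title = sprintf("%s, compound %s", object$technique, object$compound_id),
      subtitle = sprintf("intercept = %.2f, slope = %.2f, phi0 = %s",
                         object$intercept, object$slope,
                         ifelse(is.na(object$phi0), "NA",
                                sprintf("%.3f", object$phi0)))
    ) +
    ggplot2::theme_minimal()
}

#' Compare the two experimental lipophilicity indices per compound
#'
#' Dumbbell-style plot of `log kw` (RP-HPLC) against `R_M0` (RP-TLC) for
#' every compound in a fits table.
#'
#' @param fits A fits tibble with both techniques (e.g.
#'   `load_fixture_dataset()$fits`).
#' @return A ggplot object.
#' @export
plot_lipophilicity_comparison <- function(fits) {
  stopifnot(all(c("compound_id", "technique", "intercept") %in% names(fits)))
  df <- fits %>%
    mutate(compound_id = factor(.data$compound_id,
                                levels = unique(.data$compound_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compound_id, y = .data$intercept,
                                   colour = .data$technique)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$compound_id),
                       colour = "grey70") +
    ggplot2::labs(x = "compound", y = "lipophilicity index",
                  colour = NULL,
                  title = "Experimental lipophilicity: log kw vs R_M0") +
    ggplot2::theme_minimal()
}

#' Plot concordance counts of the calculated logP scales
#'
#' @param counts A tibble from [concordance_counts()].
#' @return A ggplot bar chart.
#' @export
plot_concordance <- function(counts) {
  stopifnot(all(c("calculator", "n_closest") %in% names(counts)))
  df <- mutate(counts, calculator = stats::reorder(.data$calculator,
                                                   -.data$n_closest))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$calculator, y = .data$n_closest)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "compounds with this scale closest",
                  title = "Concordance of calculated logP with experiment") +
    ggplot2::theme_minimal()
}
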