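#' Run the full lipophilicity and screening pipeline
#'
#' End-to-end orchestration: fits retention lines for whichever techniques
#' have input runs (or accepts pre-fitted line parameters), extrapolates
#' phi0, screens the experimental indices against the Lipinski lipophilicity
#' criterion, runs the calculated-logP concordance analysis when calculator
#' values are supplied, and classifies ADME descriptors when profiles are
#' supplied.
#'
#' @param hplc_runs Optional tibble of HPLC runs (see [read_hplc_csv()]).
#' @param tlc_runs Optional tibble of TLC runs (see [read_tlc_csv()]).
#' @param fits Optional tibble of pre-fitted line parameters
#'   (`compound_id`, `technique`, `intercept`, `slope`), e.g.
#'   `load_fixture_dataset()$fits`; used for compounds/techniques without
#'   raw runs. phi0 is always recomputed from intercept and slope.
#' @param calc_logp Optional tibble of the seven calculated logP scales.
#' @param adme Optional ADME profile tibble.
#' @param lipinski_threshold Pass threshold for the lipophilicity criterion
#'   (default 5).
#' @param out_dir Optional directory; when given, every result table is
#'   written there as CSV together with a plain-text `report.txt`.
#' @return A `lipo_report` list with elements `fits` (per-compound line
#'   parameters with recomputed `phi0`), `lipinski` (per compound and
#'   technique), `concordance` and `concordance_counts` (when `calc_logp`
#'   given, against the RP-HPLC index if available, else RP-TLC),
#'   `adme_class` and `adme_summary` (when `adme` given), and `log`
#'   (package version, timestamp, input hash).
#' @examples
#' ds <- load_fixture_dataset()
#' rep <- run_pipeline(fits = ds$fits, calc_logp = ds$calc_logp, adme = ds$adme)
#' @export
run_pipeline <- function(hplc_runs = NULL, tlc_runs = NULL, fits = NULL,
                         calc_logp = NULL, adme = NULL,
                         lipinski_threshold = 5, out_dir = NULL) {
  if (is.null(hplc_runs) && is.null(tlc_runs) && is.null(fits)) {
    abort("no input series: supply hplc_runs, tlc_runs, or fits")
  }

  fitted <- list()
  if (!is.null(hplc_runs)) {
    fitted$hplc <- fit_lipophilicity(build_log_k_series(hplc_runs))
  }
  if (!is.null(tlc_runs)) {
    fitted$tlc <- fit_lipophilicity(build_rm_series(tlc_runs))
  }
  if (!is.null(fits)) {
    have <- if (length(fitted) > 0) {
      bind_rows(fitted) %>% select("compound_id", "technique")
    } else {
      tibble(compound_id = character(), technique = character())
    }
    extra <- fits %>%
      mutate(compound_id = as.character(.data$compound_id)) %>%
      dplyr::anti_join(have, by = c("compound_id", "technique")) %>%
      mutate(
        phi0 = extrapolate_phi0(.data$intercept, .data$slope),
        n_points = NA_integer_, residual_sd = NA_real_
      )
    if (!"abs_correlation" %in% names(extra)) extra$abs_correlation <- NA_real_
    fitted$supplied <- extra %>%
      select("compound_id", "technique", "intercept", "slope",
             "abs_correlation", "phi0", "n_points", "residual_sd")
  }
  all_fits <- bind_rows(fitted) %>% arrange(.data$technique, .data$compound_id)

  lipinski <- all_fits %>%
    select("compound_id", "technique", "intercept") %>%
    mutate(lipinski_pass = lipinski_lipophilicity_flag(.data$intercept,
                                                       lipinski_threshold))

  report <- list(fits = all_fits, lipinski = lipinski)

  if (!is.null(calc_logp)) {
    tech <- if ("RP-HPLC" %in% all_fits$technique) "RP-HPLC" else "RP-TLC"
    experimental <- all_fits %>%
      filter(.data$technique == tech) %>%
      select("compound_id", value = "intercept")
    report$concordance <- concordance_table(experimental, calc_logp)
    report$concordance_counts <- concordance_counts(experimental, calc_logp)
  }

  if (!is.null(adme)) {
    report$adme_class <- adme %>%
      select("compound_id") %>%
      mutate(
        caco2 = classify_caco2(adme$caco2_log_papp),
        vdss = classify_vdss(adme$vdss_log),
        hia = classify_hia(adme$hia_pct),
        bbb = classify_bbb(adme$bbb_log_bb)
      )
    report$adme_summary <- adme_summary(adme)
    report$cyp_counts <- purrr::map_dfr(CYP_ISOFORMS, function(e) {
      count_cyp_inhibitors(adme, e)
    })
  }

  report$log <- list(
    package_version = as.character(utils::packageVersion("lipochrom")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    input_hash = rlang::hash(list(hplc_runs, tlc_runs, fits, calc_logp, adme,
                                  lipinski_threshold))
  )
  class(report) <- "lipo_report"

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A `lipo_report` from [run_pipeline()].
#' @param out_dir Directory (created if absent) receiving one CSV per result
#'   table and a human-readable `report.txt`.
#' @return The report, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "lipo_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("fits", "lipinski", "concordance", "concordance_counts",
              "adme_class", "adme_summary")
  for (nm in tables) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  if (!is.null(report$cyp_counts)) {
    readr::write_csv(
      mutate(report$cyp_counts,
             compounds = purrr::map_chr(.data$compounds, paste, collapse = ";")),
      file.path(out_dir, "cyp_counts.csv")
    )
  }
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

format_report <- function(report) {
  lines <- c(
    "Chromatographic lipophilicity report",
    paste0("package lipochrom ", report$log$package_version,
           " | ", report$log$timestamp),
    paste0("input hash ", report$log$input_hash),
    ""
  )
  fmt_fit <- function(df) {
    sprintf("  %-4s %-8s intercept %6.2f  slope %7.2f  phi0 %s",
            df$compound_id, df$technique, df$intercept, df$slope,
            ifelse(is.na(df$phi0), "   NA", sprintf("%6.3f", df$phi0)))
  }
  for (tech in unique(report$fits$technique)) {
    sub <- filter(report$fits, .data$technique == tech)
    rng <- summarize_range(sub$intercept)
    lines <- c(
      lines,
      sprintf("%s: %d compounds, intercept range %.2f to %.2f",
              tech, nrow(sub), rng$min, rng$max),
      fmt_fit(sub), ""
    )
  }
  n_pass <- sum(report$lipinski$lipinski_pass)
  lines <- c(lines, sprintf(
    "Lipinski lipophilicity criterion: %d of %d fits pass (logP-scale value <= 5)",
    n_pass, nrow(report$lipinski)
  ))
  fails <- filter(report$lipinski, !.data$lipinski_pass)
  if (nrow(fails) > 0) {
    lines <- c(lines, paste0("  failing: compound ", fails$compound_id,
                             " (", fails$technique, ", ",
                             sprintf("%.2f", fails$intercept), ")"))
  }
  if (!is.null(report$concordance_counts)) {
    lines <- c(lines, "", "Closest calculated logP scale (ties credited to all members):")
    cc <- report$concordance_counts
    lines <- c(lines, sprintf("  %-7s %d", cc$calculator, cc$n_closest))
  }
  if (!is.null(report$adme_summary)) {
    lines <- c(lines, "", "ADME descriptor extremes:")
    s <- report$adme_summary
    lines <- c(lines, sprintf("  %-15s min %8.3f (compound %s)  max %8.3f (compound %s)",
                              s$descriptor, s$min, s$min_compound, s$max, s$max_compound))
  }
  if (!is.null(report$cyp_counts)) {
    lines <- c(lines, "", "Predicted CYP450 inhibitors:")
    lines <- c(lines, sprintf(
      "  %-8s %d%s", report$cyp_counts$enzyme, report$cyp_counts$n_inhibitors,
      ifelse(report$cyp_counts$n_inhibitors > 0,
             paste0("  (", purrr::map_chr(report$cyp_counts$compounds,
                                          paste, collapse = ", "), ")"),
             "")
    ))
  }
  lines
}

#' @export
print.lipo_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
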