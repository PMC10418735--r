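read_checked_csv <- function(path, spec, what) {
  if (!file.exists(path)) abort(paste0(what, ": file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(names(spec$cols), header)
  missing_cols <- setdiff(missing_cols, ".default")
  if (length(missing_cols) > 0) {
    abort(paste0(what, ": missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  # parse problems are converted to structured errors below
  df <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                         show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    # problems() counts the header line; report the data row
    abort(paste0(what, ": parse error at row ", p$row - 1, ", column ", p$col,
                 " (expected ", p$expected, ", got '", p$actual, "')"))
  }
  df
}

check_numeric_col <- function(df, col, what, lower = -Inf, upper = Inf,
                              strict = FALSE) {
  v <- df[[col]]
  bad_na <- which(is.na(v))
  if (length(bad_na) > 0) {
    abort(paste0(what, ": non-numeric or missing '", col, "' at row(s) ",
                 paste(head(bad_na, 5), collapse = ", ")))
  }
  out_of_range <- if (strict) v <= lower | v >= upper else v < lower | v > upper
  bad <- which(out_of_range)
  if (length(bad) > 0) {
    abort(paste0(what, ": '", col, "' out of range at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(v)
}

#' Read chromatography and screening tables from CSV
#'
#' Typed, validated readers for the package's documented CSV schemas. Every
#' reader checks the header, numeric parsing, and physical ranges, and names
#' the offending row and column on failure.
#'
#' Schemas (one header row, `.` decimal separator):
#' * HPLC runs: `compound_id, phi, t_r_min, t_m_min, replicate`
#' * TLC runs: `compound_id, phi, r_f, replicate`
#' * calculated logP: `compound_id, milogP, AlogPs, AClogP, ALOGP, MLOGP,
#'   XLOGP2, XLOGP3`
#' * ADME profiles: `compound_id, log_s, caco2_log_papp, hia_pct, vdss_log,
#'   bbb_log_bb, fu, cyp2d6, cyp3a4, cyp1a2, cyp2c19, cyp2c9, cl_tot`
#'   (inhibition flags `Yes`/`No` or logical).
#'
#' @param path Path to a CSV file.
#' @return A tibble in the corresponding schema; CYP flags are returned as
#'   logicals.
#' @name readers
NULL

#' @rdname readers
#' @export
read_hplc_csv <- function(path) {
  df <- read_checked_csv(path, readr::cols(
    compound_id = readr::col_character(), phi = readr::col_double(),
    t_r_min = readr::col_double(), t_m_min = readr::col_double(),
    replicate = readr::col_integer()
  ), "hplc_runs")
  check_numeric_col(df, "phi", "hplc_runs", 0, 1, strict = TRUE)
  check_numeric_col(df, "t_m_min", "hplc_runs", lower = 0, strict = TRUE)
  check_numeric_col(df, "t_r_min", "hplc_runs", lower = 0, strict = TRUE)
  bad <- which(df$t_r_min <= df$t_m_min)
  if (length(bad) > 0) {
    abort(paste0("hplc_runs: t_r_min <= t_m_min at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  df
}

#' @rdname readers
#' @export
read_tlc_csv <- function(path) {
  df <- read_checked_csv(path, readr::cols(
    compound_id = readr::col_character(), phi = readr::col_double(),
    r_f = readr::col_double(), replicate = readr::col_integer()
  ), "tlc_runs")
  check_numeric_col(df, "phi", "tlc_runs", 0, 1, strict = TRUE)
  check_numeric_col(df, "r_f", "tlc_runs", 0, 1, strict = TRUE)
  df
}

#' @rdname readers
#' @export
read_calc_logp_csv <- function(path) {
  spec <- do.call(readr::cols, c(
    list(compound_id = readr::col_character()),
    setNames(rep(list(readr::col_double()), length(CALCULATORS)), CALCULATORS)
  ))
  df <- read_checked_csv(path, spec, "calc_logp")
  for (cc in CALCULATORS) check_numeric_col(df, cc, "calc_logp")
  check_compound_ids(df$compound_id, "calc_logp")
  df
}

#' @rdname readers
#' @export
read_adme_csv <- function(path) {
  cyp_cols <- tolower(CYP_ISOFORMS)
  spec <- do.call(readr::cols, c(
    list(compound_id = readr::col_character()),
    setNames(rep(list(readr::col_double()), 7),
             c("log_s", "caco2_log_papp", "hia_pct", "vdss_log",
               "bbb_log_bb", "fu", "cl_tot")),
    setNames(rep(list(readr::col_character()), 5), cyp_cols)
  ))
  df <- read_checked_csv(path, spec, "adme")
  check_numeric_col(df, "fu", "adme", 0, 1)
  check_numeric_col(df, "hia_pct", "adme", 0, 100)
  df <- mutate(df, across(all_of(cyp_cols), function(x) {
    ok <- x %in% c("Yes", "No", "TRUE", "FALSE", "yes", "no")
    if (!all(ok)) {
      abort(paste0("adme: unrecognized inhibition flag at row(s) ",
                   paste(head(which(!ok), 5), collapse = ", ")))
    }
    x %in% c("Yes", "yes", "TRUE")
  }))
  check_compound_ids(df$compound_id, "adme")
  df
}

#' Write a table in one of the documented CSV schemas
#'
#' Thin wrapper around [readr::write_csv()]; numeric columns are written at
#' full precision so a read-write round trip preserves every value.
#'
#' @param x A tibble as returned by one of the readers or by the pipeline.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_lipo_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
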