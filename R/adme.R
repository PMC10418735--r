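#' Classify Caco-2 permeability
#'
#' Predicted apparent Caco-2 monolayer permeability, a proxy for oral
#' absorption: `log Papp` (in 1e-6 cm/s) strictly greater than 0.9 counts as
#' high permeability.
#'
#' @param log_papp Numeric vector of log Papp values.
#' @return Factor with levels `low`, `high`.
#' @examples
#' classify_caco2(c(1.08, 0.9)) # high, low
#' @export
classify_caco2 <- function(log_papp) {
  stopifnot(is.numeric(log_papp), all(is.finite(log_papp)))
  factor(ifelse(log_papp > 0.9, "high", "low"), levels = c("low", "high"))
}

#' Classify the steady-state volume of distribution
#'
#' `log VDss` (L/kg) in the closed interval \[-0.15, 0.45\] is classed as an
#' optimal plasma/tissue distribution; above 0.45 the compound is expected
#' to partition predominantly into tissues, below -0.15 to stay in plasma.
#'
#' @param vdss_log Numeric vector of log VDss values.
#' @return Factor with levels `low`, `optimal`, `high`.
#' @export
classify_vdss <- function(vdss_log) {
  stopifnot(is.numeric(vdss_log), all(is.finite(vdss_log)))
  out <- ifelse(vdss_log > 0.45, "high", ifelse(vdss_log < -0.15, "low", "optimal"))
  factor(out, levels = c("low", "optimal", "high"))
}

#' Classify human intestinal absorption
#'
#' The source screen states no HIA cut-off; the default here is the pkCSM
#' convention that below 30% absorbed is poor. The threshold is exposed so
#' users can apply their own.
#'
#' @param hia_pct Percent absorbed, in \[0, 100\].
#' @param poor_below Convention threshold (default 30).
#' @return Factor with levels `poor`, `good`.
#' @export
classify_hia <- function(hia_pct, poor_below = 30) {
  stopifnot(is.numeric(hia_pct), all(is.finite(hia_pct)),
            all(hia_pct >= 0 & hia_pct <= 100))
  factor(ifelse(hia_pct < poor_below, "poor", "good"), levels = c("poor", "good"))
}

#' Classify blood-brain barrier penetration
#'
#' The source screen states no log BB cut-off; defaults follow the pkCSM
#' convention (readily crosses above 0.3, poorly distributed below -1).
#'
#' @param bbb_log_bb Numeric vector of log BB values.
#' @param readily_above,poor_below Convention thresholds (defaults 0.3, -1).
#' @return Factor with levels `poor`, `moderate`, `readily`.
#' @export
classify_bbb <- function(bbb_log_bb, readily_above = 0.3, poor_below = -1) {
  stopifnot(is.numeric(bbb_log_bb), all(is.finite(bbb_log_bb)),
            poor_below < readily_above)
  out <- ifelse(bbb_log_bb > readily_above, "readily",
                ifelse(bbb_log_bb < poor_below, "poor", "moderate"))
  factor(out, levels = c("poor", "moderate", "readily"))
}

#' Count predicted inhibitors of a CYP450 isoform
#'
#' @param profiles An ADME tibble with a `compound_id` column and logical
#'   inhibition columns `cyp2d6`, `cyp3a4`, `cyp1a2`, `cyp2c19`, `cyp2c9`
#'   (as returned in `load_fixture_dataset()$adme`).
#' @param enzyme One of `"CYP2D6"`, `"CYP3A4"`, `"CYP1A2"`, `"CYP2C19"`,
#'   `"CYP2C9"` (case-insensitive).
#' @return A one-row tibble `enzyme`, `n_inhibitors`, `compounds`
#'   (list-column of compound ids).
#' @examples
#' ds <- load_fixture_dataset()
#' count_cyp_inhibitors(ds$adme, "CYP2C19")
#' @export
count_cyp_inhibitors <- function(profiles, enzyme) {
  stopifnot(is.character(enzyme), length(enzyme) == 1)
  enzyme <- toupper(enzyme)
  if (!enzyme %in% CYP_ISOFORMS) {
    abort(paste0("invalid input: unknown enzyme '", enzyme, "'; modeled isoforms: ",
                 paste(CYP_ISOFORMS, collapse = ", ")))
  }
  col <- tolower(enzyme)
  if (!col %in% names(profiles)) {
    abort(paste0("profiles is missing the inhibition column '", col, "'"))
  }
  flags <- profiles[[col]]
  stopifnot(is.logical(flags), !anyNA(flags))
  hits <- as.character(profiles$compound_id[flags])
  tibble(enzyme = enzyme, n_inhibitors = length(hits), compounds = list(hits))
}

#' Per-descriptor extremes of an ADME profile set
#'
#' Exact minimum and maximum of every numeric ADME descriptor present, with
#' the compounds attaining them.
#'
#' @param profiles Non-empty ADME tibble with `compound_id` and any of the
#'   numeric descriptor columns `log_s`, `caco2_log_papp`, `hia_pct`,
#'   `vdss_log`, `bbb_log_bb`, `fu`, `cl_tot`.
#' @return A tibble `descriptor`, `min`, `min_compound`, `max`,
#'   `max_compound`.
#' @export
adme_summary <- function(profiles) {
  if (nrow(profiles) == 0) abort("invalid input: empty profile set")
  descriptors <- intersect(
    c("log_s", "caco2_log_papp", "hia_pct", "vdss_log", "bbb_log_bb", "fu", "cl_tot"),
    names(profiles)
  )
  if (length(descriptors) == 0) abort("profiles contain no known numeric descriptors")
  purrr::map_dfr(descriptors, function(d) {
    v <- profiles[[d]]
    stopifnot(is.numeric(v), all(is.finite(v)))
    tibble(
      descriptor = d,
      min = min(v),
      min_compound = paste(profiles$compound_id[v == min(v)], collapse = ","),
      max = max(v),
      max_compound = paste(profiles$compound_id[v == max(v)], collapse = ",")
    )
  })
}
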