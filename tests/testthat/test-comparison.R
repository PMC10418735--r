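calc_row <- function(ds, id) {
  as.list(ds$calc_logp[ds$calc_logp$compound_id == id,
                       c("milogP", "AlogPs", "AClogP", "ALOGP", "MLOGP",
                         "XLOGP2", "XLOGP3")])
}

experimental_col <- function(ds, tech) {
  df <- ds$fits[ds$fits$technique == tech, c("compound_id", "intercept")]
  names(df) <- c("compound_id", "value")
  df
}

test_that("closest calculator is found, with full tie sets", {
  ds <- fixture_dataset()
  expect_equal(closest_calculators(3.22, calc_row(ds, "7")), "MLOGP")
  expect_setequal(closest_calculators(3.60, calc_row(ds, "20")),
                  c("AlogPs", "MLOGP"))
  vals <- c(milogP = 1, AlogPs = 2, AClogP = 3, ALOGP = 4, MLOGP = 5,
            XLOGP2 = 6, XLOGP3 = 7)
  expect_equal(closest_calculators(3, vals), "AClogP")
  expect_error(closest_calculators(3, vals[-2]), "AlogPs")
  vals["MLOGP"] <- NA
  expect_error(closest_calculators(3, vals), "MLOGP")
})

test_that("closest calculator matches an independent linear scan on every compound", {
  ds <- fixture_dataset()
  for (tech in c("RP-HPLC", "RP-TLC")) {
    expcol <- experimental_col(ds, tech)
    for (i in seq_len(nrow(expcol))) {
      id <- expcol$compound_id[i]
      vals <- unlist(calc_row(ds, id))
      expect_setequal(closest_calculators(expcol$value[i], vals),
                      closest_by_scan(expcol$value[i], vals))
    }
  }
})

test_that("concordance counts credit ties and reproduce the published pattern", {
  ds <- fixture_dataset()
  counts_h <- concordance_counts(experimental_col(ds, "RP-HPLC"), ds$calc_logp)
  expect_equal(counts_h$n_closest[counts_h$calculator == "MLOGP"], 9L)

  tab_h <- concordance_table(experimental_col(ds, "RP-HPLC"), ds$calc_logp)
  mlogp_ids <- tab_h$compound_id[tab_h$calculator == "MLOGP" & tab_h$closest]
  expect_setequal(mlogp_ids, c("7", "9", "10", "11", "14", "16", "18", "20", "23"))

  # ties are credited to every member, so counts sum to >= n compounds
  expect_gte(sum(counts_h$n_closest), 28)

  # against the TLC index, AClogP attains the maximum count
  counts_t <- concordance_counts(experimental_col(ds, "RP-TLC"), ds$calc_logp)
  expect_equal(counts_t$calculator[which.max(counts_t$n_closest)], "AClogP")

  mismatched <- experimental_col(ds, "RP-HPLC")[-1, ]
  expect_error(concordance_counts(mismatched, ds$calc_logp), "compound sets")
})

test_that("Lipinski lipophilicity criterion is logP <= 5", {
  expect_false(lipinski_lipophilicity_flag(5.63))
  expect_true(lipinski_lipophilicity_flag(5.0))
  expect_true(lipinski_lipophilicity_flag(0.94))
  ds <- fixture_dataset()
  log_kw <- ds$fits$intercept[ds$fits$technique == "RP-HPLC"]
  expect_equal(sum(lipinski_lipophilicity_flag(log_kw)), 27)
})

test_that("range summaries are exact and reject empty input", {
  ds <- fixture_dataset()
  rng_h <- summarize_range(ds$fits$intercept[ds$fits$technique == "RP-HPLC"])
  expect_equal(c(rng_h$min, rng_h$max), c(1.35, 5.63))
  rng_t <- summarize_range(ds$fits$intercept[ds$fits$technique == "RP-TLC"])
  expect_equal(c(rng_t$min, rng_t$max), c(0.94, 3.56))
  single <- summarize_range(2.0)
  expect_equal(c(single$min, single$max), c(2, 2))
  expect_error(summarize_range(numeric(0)), "empty")
  withr::with_seed(3, {
    v <- rnorm(30)
    r <- summarize_range(v)
    expect_true(all(v >= r$min & v <= r$max))
  })
})

test_that("paired HPLC/TLC comparison reports differences and their sign count", {
  ds <- fixture_dataset()
  hplc <- experimental_col(ds, "RP-HPLC")
  tlc <- experimental_col(ds, "RP-TLC")
  rep <- paired_difference_report(hplc, tlc)
  expect_equal(nrow(rep), 28)
  expect_equal(attr(rep, "n_hplc_higher"), 28L)
  expect_true(all(rep$difference > 0))

  # the two propyl-chain isomers share the same log kw
  expect_equal(hplc$value[hplc$compound_id == "3"],
               hplc$value[hplc$compound_id == "4"])

  same <- paired_difference_report(hplc, hplc)
  expect_equal(attr(same, "n_hplc_higher"), 0L)
  expect_error(paired_difference_report(hplc, tlc[-3, ]), "compound sets")
})
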