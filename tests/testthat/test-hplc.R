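test_that("retention factor follows k = t_r/t_m - 1 and rejects unretained runs", {
  expect_equal(retention_factor(10, 2), 4)
  expect_equal(retention_factor(3.3, 3), 0.1)
  expect_error(retention_factor(2, 2), "invalid input")
  expect_error(retention_factor(1.5, 2), "invalid input")
  expect_error(retention_factor(10, 0), "invalid input")
  expect_error(retention_factor(10, -1), "invalid input")
})

test_that("retention factor is monotone in retention and dead time", {
  withr::with_seed(11, {
    for (i in 1:20) {
      t_m <- runif(1, 0.5, 5)
      t_r <- sort(t_m + runif(3, 0.1, 20))
      k <- retention_factor(t_r, t_m)
      expect_true(all(diff(k) > 0))
      t_m2 <- sort(runif(3, 0.2, 0.9) * min(t_r) - 1e-6)
      expect_true(all(diff(retention_factor(min(t_r), t_m2)) < 0))
    }
  })
})

test_that("log k series averages replicates on t_r before the transform", {
  runs <- tibble::tibble(
    compound_id = "a",
    phi = rep(c(0.6, 0.7, 0.8), each = 3),
    t_r_min = c(10, 10, 10, 9.8, 10.0, 10.2, 6, 6, 6),
    t_m_min = 2
  )
  series <- build_log_k_series(runs)
  expect_equal(nrow(series), 3)
  expect_equal(series$technique, rep("RP-HPLC", 3))
  # identical triplicates and a symmetric spread both average to t_r = 10
  expect_equal(series$value[series$phi == 0.6], log10(4))
  expect_equal(series$value[series$phi == 0.7], log10(4))
  expect_true(!is.unsorted(series$phi))
})

test_that("fewer than three modifier levels is an insufficient gradient", {
  runs <- tibble::tibble(compound_id = "a", phi = c(0.55, 0.60),
                         t_r_min = c(10, 8), t_m_min = 2)
  expect_error(build_log_k_series(runs), "insufficient gradient")
  expect_error(
    fit_retention_line(make_series(2, -3, c(0.5, 0.6))),
    "insufficient gradient"
  )
})

test_that("noiseless lines are recovered exactly by the fit", {
  fit <- fit_retention_line(make_series(2, -3, seq(0.55, 0.95, 0.05)))
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$slope, -3, tolerance = 1e-12)
  expect_equal(fit$abs_correlation, 1, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  # published compound-1 line parameters survive a noiseless round trip
  fit1 <- fit_retention_line(make_series(1.35, -2.975, seq(0.55, 0.95, 0.05)))
  expect_equal(fit1$intercept, 1.35, tolerance = 1e-9)
  expect_equal(fit1$slope, -2.975, tolerance = 1e-9)
  expect_equal(fit1$phi0, 1.35 / 2.975, tolerance = 1e-9)
})

test_that("OLS agrees with the normal-equation oracle on random small designs", {
  withr::with_seed(101, {
    for (i in 1:20) {
      n <- sample(3:10, 1)
      phi <- runif(n, 0.05, 0.95)
      series <- tibble::tibble(compound_id = "r", phi = phi,
                               value = rnorm(n, 1 - 2 * phi, 0.3))
      fit <- fit_retention_line(series)
      oracle <- ols_normal_equations(series$phi, series$value)
      expect_equal(fit$intercept, oracle[["intercept"]], tolerance = 1e-10)
      expect_equal(fit$slope, oracle[["slope"]], tolerance = 1e-10)
    }
  })
})

test_that("a two-point fit passes through both points when the floor is relaxed", {
  series <- tibble::tibble(compound_id = "p", phi = c(0.5, 0.7), value = c(1.0, 0.2))
  fit <- fit_retention_line(series, min_points = 2)
  slope <- (0.2 - 1.0) / (0.7 - 0.5)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0 - slope * 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept + fit$slope * series$phi, series$value, tolerance = 1e-12)
})

test_that("degenerate designs error and flat lines leave phi0 undefined", {
  same_phi <- tibble::tibble(compound_id = "d", phi = rep(0.6, 3),
                             value = c(1, 2, 3))
  expect_error(fit_retention_line(same_phi, min_points = 1), "degenerate design")

  flat <- tibble::tibble(compound_id = "f", phi = c(0.5, 0.6, 0.7), value = 1.2)
  fit <- fit_retention_line(flat)
  expect_identical(fit$slope, 0)
  expect_equal(fit$intercept, 1.2)
  expect_true(is.na(fit$phi0))
})

test_that("phi0 extrapolation reproduces the published spot values", {
  expect_equal(round(extrapolate_phi0(1.35, -2.975), 3), 0.454)
  expect_equal(round(extrapolate_phi0(5.63, -5.578), 3), 1.009)
  expect_equal(extrapolate_phi0(1.0, -2.0), 0.5)
  expect_warning(out <- extrapolate_phi0(1.0, 0), "phi0 is undefined")
  expect_true(is.na(out))
  # slope < 0 and intercept > 0 always give a positive phi0
  withr::with_seed(5, {
    expect_true(all(extrapolate_phi0(runif(50, 0.1, 6), -runif(50, 0.5, 6)) > 0))
  })
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  series <- make_series(1.35, -2.975, seq(0.55, 0.95, 0.05), compound_id = "1")
  fit <- fit_retention_line(series)

  td <- suppressWarnings(tidy(fit)) # noiseless fit: summary.lm warns
  expect_equal(td$term, c("(Intercept)", "phi"))
  expect_equal(td$estimate, c(1.35, -2.975), tolerance = 1e-9)

  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$compound_id, "1")
  expect_equal(gl$n_points, 9)

  aug <- augment(fit)
  expect_equal(aug$.resid, rep(0, 9), tolerance = 1e-10)
})

test_that("fit_lipophilicity fits every compound of a combined series table", {
  series <- dplyr::bind_rows(
    make_series(1.35, -2.975, seq(0.55, 0.95, 0.05), compound_id = "1"),
    make_series(5.63, -5.578, seq(0.55, 0.95, 0.05), compound_id = "25")
  )
  fits <- fit_lipophilicity(series, technique = "RP-HPLC")
  expect_equal(nrow(fits), 2)
  expect_equal(fits$intercept[fits$compound_id == "25"], 5.63, tolerance = 1e-9)
  expect_error(fit_retention_line(series), "mixes 2 compounds")
})
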