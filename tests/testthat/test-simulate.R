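test_that("noiseless HPLC simulation evaluates the generator formula exactly", {
  cfg <- sim_config(1.35, -2.975, phi_grid = hplc_phi_grid(), noise_sd = 0,
                    n_replicates = 1, t_m = 2)
  runs <- simulate_hplc(cfg)
  expect_equal(nrow(runs), 9)
  t_r_055 <- runs$t_r_min[runs$phi == 0.55]
  expect_equal(t_r_055, 2 * (1 + 10^(1.35 - 2.975 * 0.55)), tolerance = 1e-12)
  expect_equal(t_r_055, 3.0345, tolerance = 1e-4)

  flat <- simulate_hplc(sim_config(0, 0, noise_sd = 0, n_replicates = 2, t_m = 2))
  expect_equal(flat$t_r_min, rep(4, nrow(flat))) # k = 1 everywhere
})

test_that("noiseless TLC simulation lands at R_F = 0.5 at phi0", {
  phi0 <- 0.94 / 1.280
  cfg <- sim_config(0.94, -1.280, phi_grid = c(0.5, 0.6, phi0), noise_sd = 0,
                    n_replicates = 1)
  runs <- simulate_tlc(cfg)
  expect_equal(runs$r_f[runs$phi == phi0], 0.5, tolerance = 1e-12)
  expect_equal(runs$r_f[runs$phi == 0.5], 1 / (1 + 10^0.30), tolerance = 1e-12)
  expect_equal(round(runs$r_f[runs$phi == 0.5], 4), 0.3339)
})

test_that("simulation is deterministic given the seed and respects physical bounds", {
  cfg <- sim_config(2, -3, noise_sd = 0.5, n_replicates = 3, t_m = 1.5, seed = 42)
  expect_identical(simulate_hplc(cfg), simulate_hplc(cfg))
  expect_identical(simulate_tlc(cfg), simulate_tlc(cfg))
  expect_false(identical(simulate_hplc(cfg), simulate_hplc(cfg, seed = 43)))

  big_noise <- sim_config(0.5, -1, noise_sd = 3, n_replicates = 5, t_m = 2, seed = 7)
  h <- simulate_hplc(big_noise)
  expect_true(all(h$t_r_min > h$t_m_min))
  t <- simulate_tlc(big_noise)
  expect_true(all(t$r_f > 0 & t$r_f < 1))
})

test_that("simulator configs reject unphysical designs", {
  expect_error(sim_config(1, -2, phi_grid = c(0.5, 1.0)), "strictly in \\(0, 1\\)")
  expect_error(sim_config(1, -2, t_m = 0), "t_m")
  expect_error(sim_config(1, -2, noise_sd = -0.1))
  expect_error(sim_config(1, -2, n_replicates = 0))
})

test_that("noiseless simulate-fit round trip recovers every published parameter pair", {
  fits <- fixture_dataset()$fits
  for (i in seq_len(nrow(fits))) {
    tech <- fits$technique[i]
    grid <- if (tech == "RP-HPLC") hplc_phi_grid() else tlc_phi_grid()
    cfg <- sim_config(fits$intercept[i], fits$slope[i], phi_grid = grid,
                      noise_sd = 0, n_replicates = 1)
    fit <- if (tech == "RP-HPLC") {
      fit_retention_line(build_log_k_series(simulate_hplc(cfg)))
    } else {
      fit_rm_line(build_rm_series(simulate_tlc(cfg)))
    }
    expect_equal(fit$intercept, fits$intercept[i], tolerance = 1e-9)
    expect_equal(fit$slope, fits$slope[i], tolerance = 1e-9)
  }
})

test_that("recovery study is exact without noise and summarises a single draw as itself", {
  res0 <- recovery_study(sim_config(2, -3, noise_sd = 0, seed = 3), n_sims = 5)
  expect_equal(res0$bias, rep(0, 3), tolerance = 1e-9)
  expect_equal(res0$sd, rep(0, 3), tolerance = 1e-9)
  expect_equal(res0$n_failed, rep(0L, 3))

  cfg <- sim_config(2, -3, noise_sd = 0.05, seed = 9)
  one <- recovery_study(cfg, n_sims = 1)
  single <- fit_retention_line(build_log_k_series(simulate_hplc(
    cfg, seed = withr::with_seed(9L, sample.int(.Machine$integer.max, 1))
  )))
  expect_equal(one$bias[one$parameter == "intercept"] + 2, single$intercept)
  expect_equal(one$sd, rep(0, 3))
})

test_that("recovered-parameter spread shrinks with the noise level", {
  quiet <- recovery_study(sim_config(2, -3, noise_sd = 0.01, seed = 21), n_sims = 100)
  loud <- recovery_study(sim_config(2, -3, noise_sd = 0.05, seed = 21), n_sims = 100)
  for (p in c("intercept", "slope", "phi0")) {
    expect_lt(quiet$sd[quiet$parameter == p], loud$sd[loud$parameter == p])
  }
})

test_that("recovery study works through the TLC route too", {
  res <- recovery_study(
    sim_config(0.94, -1.28, phi_grid = tlc_phi_grid(), noise_sd = 0.02, seed = 13),
    n_sims = 50, technique = "RP-TLC"
  )
  expect_equal(nrow(res), 3)
  expect_lt(abs(res$bias[res$parameter == "intercept"]), 0.05)
  expect_equal(res$n_failed, rep(0L, 3))
})
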