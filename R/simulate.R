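#' Default modifier grids of the reference designs
#'
#' The RP-HPLC design spans methanol volume fractions 0.55-0.95, the RP-TLC
#' design 0.50-0.70, both in steps of 0.05.
#'
#' @return Numeric vector of volume fractions.
#' @export
hplc_phi_grid <- function() seq(0.55, 0.95, by = 0.05)

#' @rdname hplc_phi_grid
#' @export
tlc_phi_grid <- function() seq(0.50, 0.70, by = 0.05)

#' Configuration for the chromatography simulator
#'
#' Bundles the true retention line and design of a simulated experiment.
#' Gaussian noise is placed on the log-retention scale (log k or R_M), the
#' scale on which the fitted model is linear, so parameter-recovery
#' properties are exact and interpretable.
#'
#' @param intercept True line intercept (`log kw` / `R_M0` scale).
#' @param slope True slope per unit volume fraction (negative for realistic
#'   reversed-phase retention).
#' @param phi_grid Modifier volume fractions, each strictly in (0, 1).
#'   Defaults to the 9-level RP-HPLC grid; use [tlc_phi_grid()] for plates.
#' @param noise_sd Standard deviation of the Gaussian measurement noise on
#'   the log-retention scale (>= 0).
#' @param n_replicates Replicate measurements per grid point (>= 1;
#'   default 3, the reference designs' triplicates).
#' @param t_m Dead time in minutes (HPLC only; > 0).
#' @param seed Master integer seed; every simulation drawn from this config
#'   is reproducible given the seed.
#' @param compound_id Label attached to the simulated runs.
#' @return A validated `sim_config` object (a list).
#' @examples
#' cfg <- sim_config(1.35, -2.975, noise_sd = 0.02, seed = 1)
#' @export
sim_config <- function(intercept, slope, phi_grid = hplc_phi_grid(),
                       noise_sd = 0, n_replicates = 3L, t_m = 2,
                       seed = 1L, compound_id = "sim") {
  stopifnot(
    is.numeric(intercept), length(intercept) == 1, is.finite(intercept),
    is.numeric(slope), length(slope) == 1, is.finite(slope),
    is.numeric(phi_grid), length(phi_grid) >= 1,
    is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0,
    is.numeric(n_replicates), n_replicates >= 1,
    is.numeric(t_m), length(t_m) == 1,
    is.numeric(seed), length(seed) == 1
  )
  if (any(phi_grid <= 0 | phi_grid >= 1)) {
    abort("invalid input: all phi_grid values must lie strictly in (0, 1)")
  }
  if (t_m <= 0) abort("invalid input: t_m must be positive")
  structure(
    list(
      intercept = intercept, slope = slope, phi_grid = sort(phi_grid),
      noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
      t_m = t_m, seed = as.integer(seed), compound_id = compound_id
    ),
    class = "sim_config"
  )
}

sim_line_values <- function(config, seed) {
  phi <- rep(config$phi_grid, each = config$n_replicates)
  eps <- if (config$noise_sd == 0) {
    rep(0, length(phi))
  } else {
    withr::with_seed(seed, rnorm(length(phi), 0, config$noise_sd))
  }
  tibble(
    phi = phi,
    replicate = rep(seq_len(config$n_replicates), times = length(config$phi_grid)),
    value = config$intercept + config$slope * phi + eps
  )
}

#' Simulate RP-HPLC runs from a known retention line
#'
#' Draws `log k = intercept + slope * phi + N(0, noise_sd)` at every grid
#' point and replicate and converts back to retention times,
#' `t_r = t_m * (1 + 10^log k)`, so the simulated runs feed the same intake
#' path as real measurements.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A tibble of runs: `compound_id`, `phi`, `t_r_min`, `t_m_min`,
#'   `replicate`; deterministic given the seed, and `t_r_min > t_m_min`
#'   always.
#' @examples
#' runs <- simulate_hplc(sim_config(1.35, -2.975, noise_sd = 0))
#' @export
simulate_hplc <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sim_line_values(config, seed) %>%
    mutate(
      compound_id = config$compound_id,
      t_r_min = config$t_m * (1 + 10^.data$value),
      t_m_min = config$t_m
    ) %>%
    select("compound_id", "phi", "t_r_min", "t_m_min", "replicate")
}

#' Simulate RP-TLC runs from a known R_M line
#'
#' Draws `R_M = intercept + slope * phi + N(0, noise_sd)` and converts to
#' retardation factors through the inverse transform
#' `R_F = 1 / (1 + 10^R_M)`, which lands strictly inside (0, 1) for any
#' finite R_M.
#'
#' @inheritParams simulate_hplc
#' @return A tibble of runs: `compound_id`, `phi`, `r_f`, `replicate`.
#' @export
simulate_tlc <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sim_line_values(config, seed) %>%
    mutate(compound_id = config$compound_id, r_f = rf_from_rm(.data$value)) %>%
    select("compound_id", "phi", "r_f", "replicate")
}

recover_once <- function(config, technique, seed) {
  if (technique == "RP-HPLC") {
    series <- build_log_k_series(simulate_hplc(config, seed = seed))
    fit <- fit_retention_line(series)
  } else {
    series <- build_rm_series(simulate_tlc(config, seed = seed))
    fit <- fit_rm_line(series)
  }
  c(intercept = fit$intercept, slope = fit$slope, phi0 = fit$phi0)
}

#' Monte Carlo parameter-recovery study for the retention-line fit
#'
#' Repeatedly simulates an experiment from each configuration, runs the full
#' intake-and-fit path, and summarises how well the intercept, slope and
#' phi0 are recovered. Per-simulation seeds are drawn deterministically from
#' each config's master seed, so a study is reproducible across runs.
#'
#' @param configs A [sim_config()] or list of them.
#' @param n_sims Simulated experiments per configuration (>= 1).
#' @param technique `"RP-HPLC"` (default) or `"RP-TLC"`.
#' @return A tibble with one row per configuration and parameter:
#'   `config_id`, `parameter`, `truth`, `bias` (mean estimate minus truth),
#'   `sd` (empirical SD of the estimates), `rmse`, `n_sims`, `n_failed`
#'   (simulations whose fit errored; excluded from the summaries).
#' @examples
#' recovery_study(sim_config(2, -3, noise_sd = 0.02, seed = 7), n_sims = 50)
#' @export
recovery_study <- function(configs, n_sims, technique = c("RP-HPLC", "RP-TLC")) {
  technique <- match.arg(technique)
  stopifnot(is.numeric(n_sims), n_sims >= 1)
  n_sims <- as.integer(n_sims)
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1), "sim_config")))

  purrr::imap_dfr(configs, function(config, idx) {
    sim_seeds <- withr::with_seed(
      config$seed,
      sample.int(.Machine$integer.max, n_sims)
    )
    draws <- purrr::map(sim_seeds, function(s) {
      tryCatch(recover_once(config, technique, seed = s), error = function(e) NULL)
    })
    ok <- !vapply(draws, is.null, logical(1))
    est <- do.call(rbind, draws[ok])
    true_par <- c(
      intercept = config$intercept, slope = config$slope,
      phi0 = if (config$slope == 0) NA_real_ else -config$intercept / config$slope
    )
    purrr::map_dfr(c("intercept", "slope", "phi0"), function(p) {
      x <- est[, p]
      tibble(
        config_id = idx,
        parameter = p,
        truth = true_par[[p]],
        bias = mean(x) - true_par[[p]],
        sd = if (length(x) > 1) sd(x) else 0,
        rmse = sqrt(mean((x - true_par[[p]])^2)),
        n_sims = n_sims,
        n_failed = sum(!ok)
      )
    })
  })
}
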