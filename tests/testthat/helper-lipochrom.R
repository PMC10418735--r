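# Independent OLS oracle: closed-form normal-equation solve, kept free of
# lm() so the fit path is cross-checked against a second route.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = unname(beta[1, 1]), slope = unname(beta[2, 1]))
}

# Independent closest-calculator oracle: plain linear scan.
closest_by_scan <- function(experimental, values) {
  best <- Inf
  winners <- character()
  for (nm in names(values)) {
    d <- abs(experimental - values[[nm]])
    if (d < best) {
      best <- d
      winners <- nm
    } else if (d == best) {
      winners <- c(winners, nm)
    }
  }
  winners
}

make_series <- function(intercept, slope, phi, compound_id = "x") {
  tibble::tibble(
    compound_id = compound_id,
    phi = phi,
    value = intercept + slope * phi
  )
}

fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lipochrom::load_fixture_dataset()
    cache
  }
})
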