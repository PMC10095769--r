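# Log-log decoupling regression and the fragility-based prediction.

series_tbl <- function(temperature_K, value) {
  list(temperature_K = temperature_K, value = value)
}

test_that("an exact power law is recovered with unit R-squared", {
  temps <- seq(300, 345, by = 5)
  pred <- 10^seq(-6, 0, length.out = 10)
  fit <- decoupling_exponent(series_tbl(temps, pred),
                             series_tbl(temps, pred^(-0.5)),
                             pair_label = c("u_kin", "tau_alpha"))
  expect_equal(fit$xi, 0.5, tolerance = 1e-12)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$stderr_xi, 1e-10)
  expect_identical(fit$n_points, 10L)
})

test_that("a constant response yields a zero exponent", {
  temps <- seq(300, 340, by = 10)
  fit <- decoupling_exponent(series_tbl(temps, 10^seq(-4, 0, length.out = 5)),
                             series_tbl(temps, rep(3.7, 5)),
                             pair_label = c("u_kin", "tau_alpha"))
  expect_equal(fit$xi, 0, tolerance = 1e-14)
})

test_that("temperature matching is exact and validated", {
  a <- series_tbl(c(300, 310, 320), c(1, 2, 3))
  b <- series_tbl(c(300, 310, 330), c(1, 2, 3))
  expect_error(decoupling_exponent(a, b), "at least 3")
  neg <- series_tbl(c(300, 310, 320), c(1, -2, 3))
  expect_error(decoupling_exponent(a, neg), "positive")
})

test_that("the fitted slope equals the closed-form least-squares formula", {
  cfg <- synthetic_study_config(
    noise_sigma_log = 0.05,
    temperatures = seq(308.15, 353.15, length.out = 15), seed = 42L)
  g <- generate_growth_dataset(cfg)
  ks <- kinetic_growth_series(g, cfg$melting)
  tau <- vft_tau(ks$temperature_K, cfg$vft_truth)
  fit <- decoupling_exponent(series_tbl(ks$temperature_K, tau),
                             series_tbl(ks$temperature_K, ks$u_kin_m_per_s),
                             pair_label = c("u_kin", "tau_alpha"))
  oracle <- ols_closed_form(log10(tau), log10(ks$u_kin_m_per_s))
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit$xi, cfg$decoupling_xi_truth, tolerance = 0.05 / 0.65)
})

test_that("the exponent is invariant to rescaling either series", {
  temps <- seq(300, 345, by = 5)
  x <- 10^seq(-5, 0, length.out = 10)
  y <- 2e-7 * x^(-0.65) * 10^rnorm(10, sd = 0.02)
  base <- decoupling_exponent(series_tbl(temps, x), series_tbl(temps, y),
                              c("u_kin", "tau_alpha"))
  scaled <- decoupling_exponent(series_tbl(temps, 1e3 * x),
                                series_tbl(temps, 5 * y),
                                c("u_kin", "tau_alpha"))
  expect_equal(scaled$xi, base$xi, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(scaled$intercept, base$intercept)))
})

test_that("swapping predictor and response inverts an exact exponent", {
  temps <- seq(300, 345, by = 5)
  x <- 10^seq(-5, 0, length.out = 10)
  y <- x^(-0.65)
  fwd <- decoupling_exponent(series_tbl(temps, x), series_tbl(temps, y),
                             c("u_kin", "tau_alpha"))
  rev <- decoupling_exponent(series_tbl(temps, y), series_tbl(temps, x),
                             c("tau_alpha", "u_kin"))
  expect_equal(rev$xi, 1 / fwd$xi, tolerance = 1e-12)
})

test_that("Deming regression agrees with OLS on exact power laws", {
  temps <- seq(300, 345, by = 5)
  x <- 10^seq(-5, 0, length.out = 10)
  fit <- decoupling_exponent(series_tbl(temps, x), series_tbl(temps, x^(-0.65)),
                             c("u_kin", "tau_alpha"), method = "deming")
  expect_equal(fit$xi, 0.65, tolerance = 1e-10)
})

test_that("the fragility-based prediction is the stated line", {
  expect_equal(ediger_predicted_xi(20), 1.0)
  expect_equal(ediger_predicted_xi(220), 0.0)
  expect_equal(ediger_predicted_xi(84.6), 0.677, tolerance = 1e-12)
  expect_error(ediger_predicted_xi(-5), "positive")
})

test_that("comparison against the fragility prediction uses u_kin pairs only", {
  temps <- seq(300, 345, by = 5)
  x <- 10^seq(-5, 0, length.out = 10)
  fit <- decoupling_exponent(series_tbl(temps, x), series_tbl(temps, x^(-0.65)),
                             c("u_kin", "tau_alpha"))
  frag <- structure(list(m = 84.6, Tg = 296.15, classification = "intermediate"),
                    class = "fragility_result")
  cmp <- compare_to_ediger(fit, frag)
  expect_equal(cmp$xi_predicted, 0.677, tolerance = 1e-12)
  expect_equal(cmp$residual, 0.65 - 0.677, tolerance = 1e-10)
  gc_fit <- decoupling_exponent(series_tbl(temps, x), series_tbl(temps, x^2.2),
                                c("tau_u", "tau_beta"))
  expect_error(compare_to_ediger(gc_fit, frag), "u_kin")
})

test_that("residuals against an on-the-line truth are covered by the stderr", {
  m <- 85
  xi_line <- ediger_predicted_xi(m)  # truth placed exactly on the line
  covered <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_study_config(
      decoupling_xi_truth = xi_line, noise_sigma_log = 0.05,
      temperatures = seq(308.15, 353.15, length.out = 15), seed = 1000L + s)
    ks <- kinetic_growth_series(generate_growth_dataset(cfg), cfg$melting)
    tau <- vft_tau(ks$temperature_K, cfg$vft_truth)
    fit <- decoupling_exponent(series_tbl(ks$temperature_K, tau),
                               series_tbl(ks$temperature_K, ks$u_kin_m_per_s),
                               c("u_kin", "tau_alpha"))
    if (abs(fit$xi - xi_line) <= 1.96 * fit$stderr_xi) covered <- covered + 1L
  }
  expect_gte(covered / n_seeds, 0.85)
})

test_that("coupling exponents are classified per the activation-energy ratio", {
  expect_identical(coupling_coefficient_interpretation(1.0), "coupled")
  expect_identical(coupling_coefficient_interpretation(0.95), "coupled")
  expect_identical(coupling_coefficient_interpretation(2.20), "not controlling")
  expect_identical(coupling_coefficient_interpretation(0.65),
                   "partially decoupled")
  expect_identical(coupling_coefficient_interpretation(0), "partially decoupled")
  expect_error(coupling_coefficient_interpretation(-0.2), "non-negative")
})
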