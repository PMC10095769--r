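# The synthetic study generator: determinism, exact noiseless inversion,
# positivity, and the forward laws each downstream fit must recover.

test_that("every generator is a pure function of (config, seed)", {
  cfg <- synthetic_study_config(noise_sigma_log = 0.05, seed = 9L)
  expect_identical(generate_dielectric_spectra(cfg),
                   generate_dielectric_spectra(cfg))
  expect_identical(generate_growth_dataset(cfg), generate_growth_dataset(cfg))
  expect_identical(generate_viscosity_dataset(cfg),
                   generate_viscosity_dataset(cfg))
  expect_identical(generate_beta_relaxation(cfg), generate_beta_relaxation(cfg))
  expect_identical(generate_glassy_growth_dataset(cfg),
                   generate_glassy_growth_dataset(cfg))
  # a different seed perturbs the data
  cfg2 <- synthetic_study_config(noise_sigma_log = 0.05, seed = 10L)
  expect_false(identical(generate_growth_dataset(cfg),
                         generate_growth_dataset(cfg2)))
})

test_that("noiseless spectra peak at the VFT relaxation time", {
  shape <- list(alpha = 0.8, beta = 0.6, eps_s = 5, eps_inf = 3, sigma_dc = 0)
  cfg <- noiseless_config(hn_shape_truth = shape)
  spectra <- generate_dielectric_spectra(cfg)
  for (s in spectra[c(1, 5, 10)]) {
    f_peak_grid <- s$frequency_Hz[which.max(s$eps_imag)]
    f_expected <- 1 / (2 * pi * vft_tau(s$temperature_K, cfg$vft_truth))
    # within one grid step (10 points per decade)
    expect_lt(abs(log10(f_peak_grid) - log10(f_expected)), 0.1 + 1e-9)
  }
  expect_error(generate_dielectric_spectra(cfg, temperatures = 200), "T0")
})

test_that("the implied tau_HN places the loss peak where the inversion says", {
  # invert the peak-time conversion for alpha = 0.8, beta = 0.6 at 1 ms,
  # then confirm by numerically locating the loss maximum
  p <- hn_parameters(3, 5, 0.8, 0.6,
                     tau_hn = glassgrowth:::tau_hn_from_tau_max(1e-3, 0.8, 0.6),
                     sigma_dc = 0)
  expect_equal(p$tau_hn, 1.7399941840215033e-3, tolerance = 1e-13)
  opt <- optimize(function(lf) -hn_permittivity(p, 10^lf)$eps_imag,
                  interval = c(-2, 8), tol = 1e-10)
  expect_equal(1 / (2 * pi * 10^opt$minimum), 1e-3, tolerance = 5e-3)
})

test_that("noiseless growth encodes the decoupling exponent exactly", {
  cfg <- noiseless_config()
  g <- generate_growth_dataset(cfg, temperatures = c(313.15, 343.15))
  ks <- kinetic_growth_series(g, cfg$melting)
  tau <- vft_tau(ks$temperature_K, cfg$vft_truth)
  ratio <- log10(ks$u_kin_m_per_s[[1]] / ks$u_kin_m_per_s[[2]]) /
    log10(tau[[2]] / tau[[1]])
  expect_equal(ratio, cfg$decoupling_xi_truth, tolerance = 1e-12)
  expect_error(generate_growth_dataset(cfg, temperatures = 420.15), "below Tm")
})

test_that("generated growth vanishes as the melting point is approached", {
  cfg <- noiseless_config()
  temps <- cfg$melting$Tm - c(50, 10, 1, 1e-2, 1e-5)
  g <- generate_growth_dataset(cfg, temperatures = temps)
  # divide out the kinetic law: what remains is the driving-force factor
  tau <- vft_tau(g$temperature_K, cfg$vft_truth)
  factor <- g$u_m_per_s / (cfg$growth_prefactor * tau^(-cfg$decoupling_xi_truth))
  expect_true(all(diff(factor) < 0))  # temps sorted ascending toward Tm
  expect_lt(factor[[length(factor)]], 1e-6)
})

test_that("noiseless viscosity follows its VFT law exactly and spans decades", {
  cfg <- noiseless_config()
  v <- generate_viscosity_dataset(cfg)
  tr <- cfg$viscosity_truth
  expect_equal(log10(v$eta_Pa_s),
               log10(tr$eta0) + tr$D_eta * tr$T0_eta /
                 ((v$temperature_K - tr$T0_eta) * log(10)),
               tolerance = 1e-12)
  # the default 35-80 C window spans at least four orders of magnitude
  expect_gte(max(v$eta_Pa_s) / min(v$eta_Pa_s), 1e4)
  expect_error(generate_viscosity_dataset(cfg, temperatures = 100), "T0")
})

test_that("beta relaxation generation matches the Arrhenius ground truth", {
  cfg <- noiseless_config()
  s <- generate_beta_relaxation(cfg, temperatures = 291.15)
  expect_equal(s$tau_s, 2.0752857383353928e-7, tolerance = 1e-13)
  flat <- noiseless_config(
    beta_arrhenius_truth = arrhenius_parameters(6.31e-15, 0))
  s0 <- generate_beta_relaxation(flat, temperatures = c(250, 270, 290))
  expect_equal(s0$tau_s, rep(6.31e-15, 3))
  # log10 tau_beta exactly linear in 1/T
  s5 <- generate_beta_relaxation(cfg)
  fit <- lm(log10(s5$tau_s) ~ I(1 / s5$temperature_K))
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1, tolerance = 1e-12)
})

test_that("all generated observables are strictly positive", {
  cfg <- synthetic_study_config(noise_sigma_log = 0.1, seed = 3L)
  expect_true(all(vapply(generate_dielectric_spectra(cfg),
                         function(s) all(s$eps_imag > 0), logical(1))))
  expect_true(all(generate_growth_dataset(cfg)$u_m_per_s > 0))
  expect_true(all(generate_viscosity_dataset(cfg)$eta_Pa_s > 0))
  expect_true(all(generate_beta_relaxation(cfg)$tau_s > 0))
})

test_that("noiseless generation inverts through the downstream fits", {
  cfg <- noiseless_config()
  # relaxation-time route: VFT fit recovers the truth to 6 significant figures
  fit <- fit_vft(generate_alpha_relaxation(cfg), fix_tau0 = TRUE)
  expect_equal(fit$parameters$D, cfg$vft_truth$D, tolerance = 1e-6)
  expect_equal(fit$parameters$T0, cfg$vft_truth$T0, tolerance = 1e-6)
  # spectra route: HN fit at one temperature reproduces the VFT tau
  spec <- generate_dielectric_spectra(cfg, temperatures = 333.15)[[1]]
  hn <- fit_hn(spec)
  expect_equal(hn$tau_alpha, vft_tau(333.15, cfg$vft_truth), tolerance = 1e-4)
  expect_equal(hn$parameters$alpha, cfg$hn_shape_truth$alpha, tolerance = 1e-4)
  expect_equal(hn$parameters$beta, cfg$hn_shape_truth$beta, tolerance = 1e-4)
})

test_that("config validation enforces the stated invariants", {
  expect_error(synthetic_study_config(noise_sigma_log = -0.1), "non-negative")
  expect_error(synthetic_study_config(temperatures = c(320, 310)), "increasing")
  expect_error(synthetic_study_config(decoupling_xi_truth = 0), "positive")
  expect_error(synthetic_study_config(
    hn_shape_truth = list(alpha = 0.8, beta = 0.6, eps_s = 3, eps_inf = 5,
                          sigma_dc = 0)), "eps_s")
})
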