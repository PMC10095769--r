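# VFT law, operational Tg, fragility, AGV extrapolation, Arrhenius beta.

test_that("VFT relaxation time matches a high-precision evaluation", {
  p <- vft_parameters(tau0 = 1e-14, D = 8.5, T0 = 240)
  # exponent D*T0/(T - T0) = 34 exactly at T = 300 K; frozen evaluation
  expect_equal(vft_tau(300, p), 5.834617425274549, tolerance = 1e-14)
  # T0 -> 0 limit: tau -> tau0
  p0 <- vft_parameters(tau0 = 3e-12, D = 8.5, T0 = 1e-8)
  expect_equal(vft_tau(300, p0), 3e-12, tolerance = 1e-7)
  # strictly decreasing in T
  temps <- seq(245, 400, by = 5)
  expect_true(all(diff(vft_tau(temps, p)) < 0))
  expect_error(vft_tau(240, p), "exceed T0")
  expect_error(vft_tau(100, p), "exceed T0")
})

test_that("VFT fitting inverts noiseless synthetic series to high accuracy", {
  truth <- vft_parameters(tau0 = 1e-14, D = 8.5429, T0 = 240.4)
  temps <- seq(305, 360, by = 5)
  series <- relaxation_series(temps, vft_tau(temps, truth), "alpha")
  fit <- fit_vft(series, fix_tau0 = TRUE)
  expect_equal(fit$parameters$D, truth$D, tolerance = 1e-5)
  expect_equal(fit$parameters$T0, truth$T0, tolerance = 1e-5)
  # with tau0 free as well
  fit_free <- fit_vft(series, fix_tau0 = FALSE)
  expect_equal(fit_free$parameters$tau0, 1e-14, tolerance = 1e-3)
  expect_equal(fit_free$parameters$D, truth$D, tolerance = 1e-3)
  expect_error(fit_vft(relaxation_series(c(300, 310), c(1, 0.1), "alpha")),
               "at least 4")
})

test_that("VFT fitting recovers D and T0 from noisy series within 2%", {
  cfg <- synthetic_study_config(noise_sigma_log = 0.05, seed = 5L)
  temps <- seq(306, 361, by = 5)  # 12 temperatures
  series <- generate_alpha_relaxation(cfg, temps)
  fit <- fit_vft(series, fix_tau0 = TRUE)
  expect_equal(fit$parameters$D, cfg$vft_truth$D, tolerance = 0.02)
  expect_equal(fit$parameters$T0, cfg$vft_truth$T0, tolerance = 0.02)
})

test_that("closed-form Tg agrees with bisection root finding", {
  p <- vft_parameters(tau0 = 1e-14, D = 8.5429, T0 = 240.4)
  Tg <- glass_transition_temperature(p, tau_at_Tg = 100)
  root <- uniroot(function(Tk) log(vft_tau(Tk, p)) - log(100),
                  interval = c(p$T0 + 1e-6, 1000), tol = 1e-12)$root
  expect_equal(Tg, root, tolerance = 1e-9 / Tg)
  # the nimesulide-like defaults were built to put Tg at 23 C
  dflt <- vft_from_tg_fragility(Tg = 296.15, m = 85)
  expect_equal(glass_transition_temperature(dflt, 100), 296.15,
               tolerance = 0.01 / 296.15)
  expect_error(glass_transition_temperature(p, tau_at_Tg = 1e-14), "exceed")
})

test_that("closed-form fragility matches its finite-difference definition", {
  p <- vft_parameters(tau0 = 1e-14, D = 8.5429, T0 = 240.4)
  Tg <- glass_transition_temperature(p, 100)
  m <- fragility(p, Tg)$m
  # m = d log10(tau) / d(Tg/T) at T = Tg, by central differences
  h <- 1e-6
  g <- function(x) log10(vft_tau(Tg / x, p))  # x = Tg/T
  m_fd <- (g(1 + h) - g(1 - h)) / (2 * h)
  expect_equal(m, m_fd, tolerance = 1e-3)
  expect_error(fragility(p, Tg = 240), "exceed T0")
})

test_that("fragility approaches the Arrhenius limit 16 as T0 vanishes", {
  # keep the constraint tau(Tg) = 100 s with tau0 = 1e-14 while T0 -> 0
  Tg <- 296.15
  m_seq <- vapply(c(10, 1, 0.1), function(T0) {
    D <- log(100 / 1e-14) * (Tg - T0) / T0
    p <- vft_parameters(1e-14, D, T0)
    expect_equal(vft_tau(Tg, p), 100, tolerance = 1e-10)
    fragility(p, Tg)$m
  }, numeric(1))
  expect_true(all(diff(m_seq) < 0))
  expect_equal(m_seq[[3]], 16, tolerance = 1e-3)
})

test_that("the nimesulide-like defaults give an intermediate glass former", {
  p <- vft_from_tg_fragility(Tg = 296.15, m = 85)
  fr <- fragility(p, glass_transition_temperature(p, 100))
  expect_equal(fr$m, 85, tolerance = 0.01)
  expect_identical(fr$classification, "intermediate")
  # classification thresholds
  strong <- vft_from_tg_fragility(296.15, 20)
  expect_identical(fragility(strong, glass_transition_temperature(strong, 100))$classification,
                   "strong")
  fragile <- vft_from_tg_fragility(296.15, 120)
  expect_identical(fragility(fragile, glass_transition_temperature(fragile, 100))$classification,
                   "fragile")
})

test_that("fragility depends only on D and T0/Tg", {
  p1 <- vft_parameters(1e-14, 8.5, 240)
  p2 <- vft_parameters(1e-10, 8.5, 480)   # tau0 rescaled, T0 and Tg doubled
  expect_equal(fragility(p1, 300)$m, fragility(p2, 600)$m, tolerance = 1e-14)
})

test_that("AGV reduces to VFT for the equilibrated glass and at Tg", {
  p <- vft_from_tg_fragility(296.15, 85)
  Tg <- 296.15
  temps <- seq(250, 295, by = 5)
  for (Tk in temps) {
    expect_equal(agv_tau(Tk, agv_state(p, T_f = Tk)), vft_tau(Tk, p),
                 tolerance = 1e-12)
  }
  expect_equal(agv_tau(Tg, agv_state(p, T_f = Tg)), 100, tolerance = 1e-10)
  expect_error(agv_state(p, T_f = p$T0 - 1), "exceed T0")
})

test_that("the fresh-glass branch is Arrhenius and lies below the equilibrated one", {
  p <- vft_from_tg_fragility(296.15, 85)
  Tg <- 296.15
  fresh <- agv_state(p, T_f = Tg)
  temps <- seq(245, 295, by = 2.5)
  tau_fresh <- agv_tau(temps, fresh)
  tau_equil <- vft_tau(temps, p)
  expect_true(all(tau_fresh < tau_equil))
  expect_equal(agv_tau(Tg, fresh), vft_tau(Tg, p), tolerance = 1e-14)
  # log10 tau exactly linear in 1/T below Tg
  fit <- lm(log10(tau_fresh) ~ I(1 / temps))
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1, tolerance = 1e-12)
})

test_that("Arrhenius beta-relaxation times match a high-precision evaluation", {
  p <- arrhenius_parameters(tau_inf = 6.31e-15, delta_E = 41.9e3)
  frozen <- c("273.15" = 6.4928489773878458e-7,
              "278.15" = 4.6602047159014080e-7,
              "283.15" = 3.3842419352980918e-7,
              "288.15" = 2.4850763092828787e-7,
              "291.15" = 2.0752857383353928e-7)
  for (Tc in names(frozen)) {
    expect_equal(arrhenius_tau(as.numeric(Tc), p), frozen[[Tc]],
                 tolerance = 1e-13)
  }
  flat <- arrhenius_parameters(tau_inf = 2e-12, delta_E = 0)
  expect_equal(arrhenius_tau(c(100, 200, 300), flat), rep(2e-12, 3))
  expect_error(arrhenius_tau(-1, p), "positive")
  # exact log-linearity in 1/T
  temps <- seq(250, 300, by = 10)
  fit <- lm(log10(arrhenius_tau(temps, p)) ~ I(1 / temps))
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1, tolerance = 1e-12)
})

test_that("Arrhenius fitting inverts its own model", {
  p <- arrhenius_parameters(tau_inf = 6.31e-15, delta_E = 41.9e3)
  temps <- seq(263, 293, by = 5)
  fit <- fit_arrhenius(relaxation_series(temps, arrhenius_tau(temps, p), "beta"))
  expect_equal(fit$parameters$tau_inf, p$tau_inf, tolerance = 1e-8)
  expect_equal(fit$parameters$delta_E, p$delta_E, tolerance = 1e-8)
  expect_equal(fit$diagnostics$r_squared, 1, tolerance = 1e-12)
})
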