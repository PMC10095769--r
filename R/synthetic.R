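#' Synthetic study configuration
#'
#' Ground-truth parameters for a complete synthetic study of a
#' nimesulide-like glass-forming drug. Every downstream analysis stage can
#' be exercised against data generated from this config, with the
#' generating values known exactly.
#'
#' The defaults describe the emulated material, not any published
#' parameter set (no VFT triple for nimesulide is available in the
#' literature the package draws on; the values here are synthetic):
#' * alpha-relaxation: VFT with tau0 = 1e-14 s, solved (via
#'   [vft_from_tg_fragility()]) so that tau(Tg) = 100 s at Tg = 296.15 K
#'   (23 C) with fragility m = 85 — an intermediate glass former.
#' * crystal growth: u(T) = C * tau_alpha(T)^(-xi) * f(T) with
#'   decoupling exponent xi = 0.65, prefactor C = 1e-11 m/s s^xi, and
#'   f(T) the driving-force factor for Tm = 420.15 K (147 C) and
#'   delta_Sm = 80 J/(mol K).
#' * dielectric loss: one HN process (alpha = 0.8, beta = 0.6,
#'   eps_s = 5, eps_inf = 3) plus dc conductivity 1e-11 S/m, on a
#'   log-spaced 0.1 Hz - 1 MHz grid.
#' * viscosity: its own VFT triple, mildly decoupled from tau_alpha
#'   (zero-mobility temperature a few K below that of tau_alpha, scaled
#'   to reach 1e12 Pa s at Tg). Pass
#'   `viscosity_truth = viscosity_truth_coupled(vft_truth)` for a
#'   viscosity that tracks tau_alpha exactly.
#' * beta relaxation: Arrhenius with tau_inf = 6.31e-15 s and
#'   delta_E = 41.9 kJ/mol.
#' * glassy-state (glass-to-crystal) growth: layer times coupled to the
#'   beta relaxation as log10(tau_u) = 2.20 * log10(tau_beta) + 14.
#' * noise: multiplicative lognormal — Gaussian of width
#'   `noise_sigma_log` on log10 of every positive observable.
#'
#' @param vft_truth [vft_parameters()] for the alpha relaxation
#' @param decoupling_xi_truth growth decoupling exponent (> 0)
#' @param growth_prefactor C in u_kin = C * tau_alpha^(-xi) (m/s s^xi)
#' @param melting a [melting_thermo()]
#' @param hn_shape_truth list with `alpha`, `beta`, `eps_s`, `eps_inf`,
#'   `sigma_dc`
#' @param beta_arrhenius_truth [arrhenius_parameters()] for the beta
#'   process
#' @param viscosity_truth list with `eta0` (Pa s), `D_eta`, `T0_eta` (K)
#' @param gc_coupling_truth list with `xi` and `log10_A` for the
#'   glassy-state layer-time law log10(tau_u) = xi*log10(tau_beta) + A
#' @param geometry a [molecular_geometry()]
#' @param noise_sigma_log std of the Gaussian noise on log10 observables
#' @param temperatures supercooled-liquid temperature grid (K, strictly
#'   increasing)
#' @param glassy_temperatures glassy-state temperature grid (K)
#' @param frequencies_per_decade points per decade of the dielectric
#'   frequency grid
#' @param freq_range_Hz dielectric frequency window (Hz)
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed)
#' @return an object of class `synthetic_study_config`
#' @export
synthetic_study_config <- function(
    vft_truth = vft_from_tg_fragility(Tg = 296.15, m = 85),
    decoupling_xi_truth = 0.65,
    growth_prefactor = 1e-11,
    melting = melting_thermo(Tm = 420.15, delta_Sm = 80),
    hn_shape_truth = list(alpha = 0.8, beta = 0.6, eps_s = 5, eps_inf = 3,
                          sigma_dc = 1e-11),
    beta_arrhenius_truth = arrhenius_parameters(tau_inf = 6.31e-15,
                                                delta_E = 41.9e3),
    viscosity_truth = NULL,
    gc_coupling_truth = list(xi = 2.20, log10_A = 14),
    geometry = molecular_geometry(V_A3 = 244),
    noise_sigma_log = 0.02,
    temperatures = kelvin_from_celsius(seq(35, 80, by = 5)),
    glassy_temperatures = kelvin_from_celsius(c(0, 5, 10, 15, 18)),
    frequencies_per_decade = 10L,
    freq_range_Hz = c(0.1, 1e6),
    seed = 1L) {
  stopifnot(inherits(vft_truth, "vft_parameters"),
            inherits(melting, "melting_thermo"),
            inherits(beta_arrhenius_truth, "arrhenius_parameters"),
            inherits(geometry, "molecular_geometry"))
  if (is.null(viscosity_truth)) {
    viscosity_truth <- viscosity_truth_decoupled(vft_truth)
  }
  assert_that(decoupling_xi_truth > 0, "decoupling_xi_truth must be positive")
  assert_that(growth_prefactor > 0, "growth_prefactor must be positive")
  assert_that(noise_sigma_log >= 0, "noise_sigma_log must be non-negative")
  assert_that(all(diff(temperatures) > 0),
              "temperatures must be strictly increasing")
  assert_that(all(diff(glassy_temperatures) > 0),
              "glassy_temperatures must be strictly increasing")
  assert_that(all(unlist(viscosity_truth) > 0),
              "viscosity_truth parameters must be positive")
  assert_that(frequencies_per_decade >= 2,
              "frequencies_per_decade must be at least 2")
  assert_that(length(freq_range_Hz) == 2L && all(freq_range_Hz > 0) &&
                freq_range_Hz[[2L]] > freq_range_Hz[[1L]],
              "freq_range_Hz must be an increasing positive pair")
  h <- hn_shape_truth
  assert_that(all(c("alpha", "beta", "eps_s", "eps_inf", "sigma_dc") %in% names(h)),
              "hn_shape_truth must name alpha, beta, eps_s, eps_inf, sigma_dc")
  assert_that(h$alpha > 0 && h$alpha <= 1 && h$beta > 0 && h$beta <= 1,
              "HN shape parameters must lie in (0, 1]")
  assert_that(h$eps_s > h$eps_inf && h$eps_inf > 0 && h$sigma_dc >= 0,
              "need eps_s > eps_inf > 0 and sigma_dc >= 0")
  g <- gc_coupling_truth
  assert_that(all(c("xi", "log10_A") %in% names(g)) && g$xi > 0,
              "gc_coupling_truth must name a positive xi and log10_A")
  structure(
    list(vft_truth = vft_truth, decoupling_xi_truth = decoupling_xi_truth,
         growth_prefactor = growth_prefactor, melting = melting,
         hn_shape_truth = h, beta_arrhenius_truth = beta_arrhenius_truth,
         viscosity_truth = viscosity_truth, gc_coupling_truth = g,
         geometry = geometry, noise_sigma_log = noise_sigma_log,
         temperatures = as.numeric(temperatures),
         glassy_temperatures = as.numeric(glassy_temperatures),
         frequencies_per_decade = as.integer(frequencies_per_decade),
         freq_range_Hz = as.numeric(freq_range_Hz),
         seed = as.integer(seed)),
    class = "synthetic_study_config")
}

#' @export
print.synthetic_study_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study_config> xi = %.3g, noise sigma(log10) = %.3g, ",
                     "%d liquid + %d glassy temperatures, seed %d\n"),
              x$decoupling_xi_truth, x$noise_sigma_log, length(x$temperatures),
              length(x$glassy_temperatures), x$seed))
  print(x$vft_truth)
  invisible(x)
}

#' Viscosity ground truth, mildly decoupled from the alpha relaxation
#'
#' A VFT triple for the viscosity whose zero-mobility temperature sits
#' `delta_T0` kelvin below that of the alpha relaxation, scaled so the
#' viscosity reaches `eta_at_Tg` at the Tg implied by `vft_truth`. The
#' small T0 offset gives a slight, systematic decoupling between eta and
#' tau_alpha of the kind seen when oscillatory-flow viscosities are
#' related to steady shear.
#'
#' @param vft_truth the alpha-relaxation [vft_parameters()]
#' @param eta0 high-temperature limit viscosity (Pa s)
#' @param eta_at_Tg viscosity at Tg (Pa s), conventionally 1e12
#' @param delta_T0 offset of the viscosity T0 below the relaxation T0 (K)
#' @param tau_at_Tg Tg convention used to locate Tg from `vft_truth` (s)
#' @return list with `eta0`, `D_eta`, `T0_eta`
#' @export
viscosity_truth_decoupled <- function(vft_truth, eta0 = 1e-4, eta_at_Tg = 1e12,
                                      delta_T0 = 2.4, tau_at_Tg = 100) {
  Tg <- glass_transition_temperature(vft_truth, tau_at_Tg)
  T0_eta <- vft_truth$T0 - delta_T0
  assert_that(T0_eta > 0, "viscosity T0 must stay positive")
  D_eta <- log(eta_at_Tg / eta0) * (Tg - T0_eta) / T0_eta
  list(eta0 = eta0, D_eta = D_eta, T0_eta = T0_eta)
}

#' Viscosity ground truth exactly coupled to the alpha relaxation
#'
#' Shares (D, T0) with the alpha-relaxation VFT, so log(eta) and
#' log(tau_alpha) are affinely related and every power law in tau_alpha
#' is exactly a power law in eta with the same exponent.
#'
#' @param vft_truth the alpha-relaxation [vft_parameters()]
#' @param eta0 high-temperature limit viscosity (Pa s)
#' @return list with `eta0`, `D_eta`, `T0_eta`
#' @export
viscosity_truth_coupled <- function(vft_truth, eta0 = 1e-4) {
  list(eta0 = eta0, D_eta = vft_truth$D, T0_eta = vft_truth$T0)
}

# multiplicative lognormal noise: x * 10^N(0, sigma), seeded
apply_log_noise <- function(x, sigma, seed) {
  if (sigma == 0) return(x)
  withr::with_seed(seed, x * 10^rnorm(length(x), sd = sigma))
}

# the log-spaced frequency grid of the emulated instrument
frequency_grid <- function(config) {
  lo <- log10(config$freq_range_Hz[[1L]])
  hi <- log10(config$freq_range_Hz[[2L]])
  n <- round((hi - lo) * config$frequencies_per_decade) + 1L
  assert_that(n >= 2, "frequency grid is empty")
  10^seq(lo, hi, length.out = n)
}

#' Generate synthetic dielectric spectra
#'
#' One spectrum per configured temperature: the HN shape from
#' `hn_shape_truth` with tau_HN chosen so that the derived loss-peak time
#' tau_max equals the VFT ground-truth tau_alpha(T), plus the dc
#' conductivity term, with multiplicative lognormal noise on both
#' permittivity parts. Deterministic given the config seed.
#'
#' @param config a [synthetic_study_config()]
#' @param temperatures temperature grid (K), defaulting to the config's;
#'   all must exceed the VFT T0
#' @return list of [dielectric_spectrum()] objects
#' @export
generate_dielectric_spectra <- function(config,
                                        temperatures = config$temperatures) {
  stopifnot(inherits(config, "synthetic_study_config"))
  assert_that(all(temperatures > config$vft_truth$T0),
              "temperatures must exceed the VFT T0 (tau undefined below)")
  f <- frequency_grid(config)
  h <- config$hn_shape_truth
  out <- vector("list", length(temperatures))
  for (i in seq_along(temperatures)) {
    Tk <- temperatures[[i]]
    tau_max <- vft_tau(Tk, config$vft_truth)
    tau_hn <- tau_hn_from_tau_max(tau_max, h$alpha, h$beta)
    p <- hn_parameters(eps_inf = h$eps_inf, eps_s = h$eps_s, alpha = h$alpha,
                       beta = h$beta, tau_hn = tau_hn, sigma_dc = h$sigma_dc)
    mod <- hn_permittivity(p, f)
    er <- apply_log_noise(mod$eps_real, config$noise_sigma_log,
                          config$seed + 101L + 7L * i)
    ei <- apply_log_noise(mod$eps_imag, config$noise_sigma_log,
                          config$seed + 102L + 7L * i)
    out[[i]] <- dielectric_spectrum(Tk, f, er, ei)
  }
  out
}

#' Generate a synthetic crystal growth dataset
#'
#' u(T) = C * tau_alpha(T)^(-xi) * (1 - exp(-delta_Sm*(Tm - T)/(R*T)))
#' with multiplicative lognormal noise; the forward direction of the
#' decoupling law the analysis later inverts.
#'
#' @param config a [synthetic_study_config()]
#' @param temperatures temperature grid (K), all strictly below Tm
#' @return a bulk [growth_rate_series()]
#' @export
generate_growth_dataset <- function(config, temperatures = config$temperatures) {
  stopifnot(inherits(config, "synthetic_study_config"))
  assert_that(all(temperatures < config$melting$Tm),
              "growth temperatures must lie below Tm")
  tau <- vft_tau(temperatures, config$vft_truth)
  factor <- 1 - exp(-config$melting$delta_Sm * (config$melting$Tm - temperatures) /
                      (config$melting$R * temperatures))
  u <- config$growth_prefactor * tau^(-config$decoupling_xi_truth) * factor
  u <- apply_log_noise(u, config$noise_sigma_log, config$seed + 201L)
  growth_rate_series(temperatures, u, environment = "bulk")
}

#' Generate a synthetic glassy-state (glass-to-crystal) growth dataset
#'
#' Layer times coupled to the beta relaxation,
#' log10(tau_u) = xi * log10(tau_beta) + A, converted to growth rates via
#' u = d / tau_u; emulates the fast glass-to-crystal growth mode whose
#' activation energy exceeds that of the secondary relaxation.
#'
#' @param config a [synthetic_study_config()]
#' @param temperatures glassy temperature grid (K)
#' @return a bulk [growth_rate_series()]
#' @export
generate_glassy_growth_dataset <- function(config,
                                           temperatures = config$glassy_temperatures) {
  stopifnot(inherits(config, "synthetic_study_config"))
  tau_beta <- arrhenius_tau(temperatures, config$beta_arrhenius_truth)
  g <- config$gc_coupling_truth
  tau_u <- 10^(g$log10_A + g$xi * log10(tau_beta))
  u <- (config$geometry$d_A * 1e-10) / tau_u
  u <- apply_log_noise(u, config$noise_sigma_log, config$seed + 301L)
  growth_rate_series(temperatures, u, environment = "bulk")
}

#' Generate a synthetic viscosity dataset
#'
#' VFT-form eta(T) from `viscosity_truth` with multiplicative lognormal
#' noise: log10(eta) = log10(eta0) + D_eta*T0_eta/((T - T0_eta)*ln 10).
#'
#' @param config a [synthetic_study_config()]
#' @param temperatures temperature grid (K), all above the viscosity T0
#' @return a [viscosity_series()]
#' @export
generate_viscosity_dataset <- function(config, temperatures = config$temperatures) {
  stopifnot(inherits(config, "synthetic_study_config"))
  v <- config$viscosity_truth
  assert_that(all(temperatures > v$T0_eta),
              "temperatures must exceed the viscosity T0")
  eta <- v$eta0 * exp(v$D_eta * v$T0_eta / (temperatures - v$T0_eta))
  eta <- apply_log_noise(eta, config$noise_sigma_log, config$seed + 401L)
  viscosity_series(temperatures, eta)
}

#' Generate synthetic beta-relaxation times
#'
#' Arrhenius tau_beta(T) from `beta_arrhenius_truth` with multiplicative
#' lognormal noise.
#'
#' @param config a [synthetic_study_config()]
#' @param temperatures temperature grid (K), defaulting to the glassy grid
#' @return a beta-process [relaxation_series()]
#' @export
generate_beta_relaxation <- function(config,
                                     temperatures = config$glassy_temperatures) {
  stopifnot(inherits(config, "synthetic_study_config"))
  tau <- arrhenius_tau(temperatures, config$beta_arrhenius_truth)
  tau <- apply_log_noise(tau, config$noise_sigma_log, config$seed + 501L)
  relaxation_series(temperatures, tau, process = "beta")
}

#' Generate synthetic alpha-relaxation times
#'
#' Direct VFT tau_alpha(T) with multiplicative lognormal noise, for
#' studies that carry precomputed relaxation times instead of raw
#' spectra.
#'
#' @param config a [synthetic_study_config()]
#' @param temperatures temperature grid (K), all above the VFT T0
#' @return an alpha-process [relaxation_series()]
#' @export
generate_alpha_relaxation <- function(config, temperatures = config$temperatures) {
  stopifnot(inherits(config, "synthetic_study_config"))
  assert_that(all(temperatures > config$vft_truth$T0),
              "temperatures must exceed the VFT T0")
  tau <- vft_tau(temperatures, config$vft_truth)
  tau <- apply_log_noise(tau, config$noise_sigma_log, config$seed + 601L)
  relaxation_series(temperatures, tau, process = "alpha")
}
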