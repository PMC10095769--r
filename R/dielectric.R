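#' Dielectric spectrum at one temperature
#'
#' Container for a measured complex-permittivity spectrum: the real part
#' eps' and imaginary (loss) part eps'' on a common frequency grid, at a
#' single temperature. Frequencies are ordinary frequencies in Hz; the
#' angular frequency omega = 2*pi*f is applied internally wherever the
#' relaxation model needs it.
#'
#' @param temperature_K temperature of the measurement (K)
#' @param frequency_Hz strictly increasing frequencies (Hz), length >= 8
#' @param eps_real real part of the permittivity (dimensionless, > 0)
#' @param eps_imag imaginary part / dielectric loss (dimensionless)
#' @return an object of class `dielectric_spectrum`
#' @export
dielectric_spectrum <- function(temperature_K, frequency_Hz, eps_real, eps_imag) {
  assert_that(length(temperature_K) == 1L && is.finite(temperature_K) &&
                temperature_K > 0, "temperature_K must be a single positive number")
  n <- length(frequency_Hz)
  assert_that(n >= 8L, "a spectrum needs at least 8 frequency points")
  assert_that(length(eps_real) == n && length(eps_imag) == n,
              "frequency_Hz, eps_real and eps_imag must have equal length")
  assert_that(all(frequency_Hz > 0), "frequencies must be positive")
  assert_that(all(diff(frequency_Hz) > 0), "frequencies must be strictly increasing")
  assert_that(all(eps_real > 0), "eps_real must be positive")
  structure(
    list(temperature_K = temperature_K,
         frequency_Hz = as.numeric(frequency_Hz),
         eps_real = as.numeric(eps_real),
         eps_imag = as.numeric(eps_imag)),
    class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("<dielectric_spectrum> T = %.2f K (%.2f C), %d frequencies [%g, %g] Hz\n",
              x$temperature_K, celsius_from_kelvin(x$temperature_K),
              length(x$frequency_Hz), min(x$frequency_Hz), max(x$frequency_Hz)))
  invisible(x)
}

#' Havriliak-Negami model parameters
#'
#' Parameters of the Havriliak-Negami (HN) relaxation function with a
#' dc-conductivity term,
#' eps*(omega) = eps_inf + (eps_s - eps_inf) / (1 + (i omega tau_HN)^alpha)^beta
#'             + sigma_dc / (i omega eps_0),
#' where alpha and beta are the width and asymmetry shape parameters
#' (both in (0, 1]; alpha = beta = 1 recovers the Debye model, beta = 1
#' the symmetric Cole-Cole model).
#'
#' @param eps_inf high-frequency limit permittivity (> 0)
#' @param eps_s static permittivity (> eps_inf)
#' @param alpha width shape parameter, in (0, 1]
#' @param beta asymmetry shape parameter, in (0, 1]
#' @param tau_hn HN relaxation time (s, > 0)
#' @param sigma_dc dc conductivity (S/m, >= 0)
#' @return an object of class `hn_parameters`
#' @export
hn_parameters <- function(eps_inf, eps_s, alpha, beta, tau_hn, sigma_dc = 0) {
  assert_that(eps_inf > 0, "eps_inf must be positive")
  assert_that(eps_s > eps_inf, "eps_s must exceed eps_inf")
  assert_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  assert_that(beta > 0 && beta <= 1, "beta must lie in (0, 1]")
  assert_that(tau_hn > 0, "tau_hn must be positive")
  assert_that(sigma_dc >= 0, "sigma_dc must be non-negative")
  structure(
    list(eps_inf = eps_inf, eps_s = eps_s, alpha = alpha, beta = beta,
         tau_hn = tau_hn, sigma_dc = sigma_dc, eps0 = eps0_vacuum),
    class = "hn_parameters")
}

#' @export
print.hn_parameters <- function(x, ...) {
  cat(sprintf(paste0("<hn_parameters> eps_inf = %.4g, eps_s = %.4g, ",
                     "alpha = %.4g, beta = %.4g, tau_HN = %.4g s, sigma_dc = %.4g S/m\n"),
              x$eps_inf, x$eps_s, x$alpha, x$beta, x$tau_hn, x$sigma_dc))
  invisible(x)
}

#' Evaluate the Havriliak-Negami model
#'
#' Complex permittivity of the HN model plus dc-conductivity term at the
#' given ordinary frequencies. The complex power uses the principal
#' branch; the conductivity term sigma_dc/(omega eps_0) contributes to the
#' loss eps'' only, never to eps'.
#'
#' @param params an [hn_parameters()] object
#' @param frequency_Hz frequencies (Hz, > 0); vectorized
#' @return a data.frame with columns `frequency_Hz`, `eps_real`, `eps_imag`
#' @export
hn_permittivity <- function(params, frequency_Hz) {
  stopifnot(inherits(params, "hn_parameters"))
  assert_that(all(frequency_Hz > 0), "frequency must be positive")
  omega <- 2 * pi * frequency_Hz
  z <- (1i * omega * params$tau_hn)^params$alpha
  hn <- params$eps_inf + (params$eps_s - params$eps_inf) / (1 + z)^params$beta
  # eps* = eps' - i eps'': loss is minus the imaginary part of the HN term
  data.frame(frequency_Hz = frequency_Hz,
             eps_real = Re(hn),
             eps_imag = -Im(hn) + params$sigma_dc / (omega * params$eps0))
}

#' Alpha-relaxation time from HN parameters
#'
#' Converts a fitted HN relaxation time to the model-free relaxation time
#' tau_max = 1/(2 pi f_peak), the inverse angular frequency of the loss
#' maximum of the conductivity-free HN curve:
#' tau_max = tau_HN * sin(pi a / (2 + 2b))^(-1/a) * sin(pi a b / (2 + 2b))^(1/a).
#' For the Debye (a = b = 1) and Cole-Cole (b = 1) cases both sine factors
#' cancel and tau_max = tau_HN exactly.
#'
#' @param params an [hn_parameters()] object, or a numeric tau_hn when
#'   `alpha` and `beta` are given explicitly
#' @param alpha,beta shape parameters, used when `params` is numeric
#' @return tau_max in seconds
#' @export
tau_alpha_from_hn <- function(params, alpha = NULL, beta = NULL) {
  if (inherits(params, "hn_parameters")) {
    tau_hn <- params$tau_hn; a <- params$alpha; b <- params$beta
  } else {
    tau_hn <- params; a <- alpha; b <- beta
  }
  assert_that(!is.null(a) && !is.null(b), "alpha and beta are required")
  assert_that(a > 0 && a <= 1, "alpha must lie in (0, 1]")
  assert_that(b > 0 && b <= 1, "beta must lie in (0, 1]")
  assert_that(all(tau_hn > 0), "tau_hn must be positive")
  tau_hn * sin(pi * a / (2 + 2 * b))^(-1 / a) * sin(pi * a * b / (2 + 2 * b))^(1 / a)
}

# inverse of tau_alpha_from_hn: the tau_HN whose loss peak sits at tau_max
tau_hn_from_tau_max <- function(tau_max, alpha, beta) {
  tau_max * sin(pi * alpha / (2 + 2 * beta))^(1 / alpha) *
    sin(pi * alpha * beta / (2 + 2 * beta))^(-1 / alpha)
}

#' Options for the HN fit
#'
#' @param n_tau_starts number of multi-start initial values for log10
#'   tau_HN, spread across the inverse of the measured frequency window
#' @param maxiter maximum Levenberg-Marquardt iterations per start
#' @param alpha_min lower bound for the shape parameters
#' @return a list of options for [fit_hn()]
#' @export
hn_fit_options <- function(n_tau_starts = 7L, maxiter = 200L, alpha_min = 0.05) {
  list(n_tau_starts = as.integer(n_tau_starts), maxiter = as.integer(maxiter),
       alpha_min = alpha_min)
}

#' Fit the Havriliak-Negami model to a dielectric spectrum
#'
#' Joint least-squares fit of eps' and eps'' with relative residual
#' weighting (the loss spans decades across the frequency window, so
#' absolute residuals would be dominated by the low-frequency conductivity
#' tail). A single HN process plus dc conductivity is fitted; the strength
#' is parameterized as delta_eps = eps_s - eps_inf > 0 so the static
#' permittivity always exceeds the high-frequency limit. Multi-start over
#' log10 tau_HN guards against the loss peak being mistaken for the
#' conductivity wing; the restart with the smallest residual norm wins,
#' ties broken by the smallest tau_HN.
#'
#' @param spectrum a [dielectric_spectrum()]
#' @param options an [hn_fit_options()] list
#' @return a list of class `hn_fit` with elements `parameters`
#'   ([hn_parameters()]), `tau_alpha` (s) and `diagnostics` (class
#'   `fit_diagnostics`: residual norm, restarts used, convergence flag,
#'   per-parameter standard errors where available)
#' @export
fit_hn <- function(spectrum, options = hn_fit_options()) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  f <- spectrum$frequency_Hz
  assert_that(log10(max(f) / min(f)) >= 2,
              "the spectrum must span at least 2 frequency decades")
  obs_r <- spectrum$eps_real
  obs_i <- spectrum$eps_imag
  # relative weights with a floor so near-zero loss points cannot blow up
  w_r <- pmax(abs(obs_r), 1e-3 * max(abs(obs_r)))
  w_i <- pmax(abs(obs_i), 1e-3 * max(abs(obs_i)))

  resid_fun <- function(par) {
    p <- hn_parameters(eps_inf = par[[1L]], eps_s = par[[1L]] + par[[2L]],
                       alpha = par[[3L]], beta = par[[4L]],
                       tau_hn = 10^par[[5L]], sigma_dc = par[[6L]])
    mod <- hn_permittivity(p, f)
    c((mod$eps_real - obs_r) / w_r, (mod$eps_imag - obs_i) / w_i)
  }

  lt_lo <- -log10(2 * pi * max(f))
  lt_hi <- -log10(2 * pi * min(f))
  tau_starts <- seq(lt_lo, lt_hi, length.out = options$n_tau_starts)
  eps_inf0 <- max(min(obs_r), 1e-3)
  deps0 <- max(max(obs_r) - min(obs_r), 1e-3)
  lower <- c(1e-6, 1e-6, options$alpha_min, options$alpha_min, lt_lo - 2, 0)
  upper <- c(Inf, Inf, 1, 1, lt_hi + 2, Inf)

  best <- NULL
  n_used <- 0L
  for (lt0 in tau_starts) {
    n_used <- n_used + 1L
    start <- c(eps_inf0, deps0, 0.8, 0.8, lt0, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn - 1e-12 ||
        (abs(rn - best$rn) <= 1e-12 && fit$par[[5L]] < best$fit$par[[5L]])) {
      best <- list(fit = fit, rn = rn)
    }
  }
  assert_that(!is.null(best), "HN fit failed at every restart")

  par <- best$fit$par
  params <- hn_parameters(eps_inf = par[[1L]], eps_s = par[[1L]] + par[[2L]],
                          alpha = par[[3L]], beta = par[[4L]],
                          tau_hn = 10^par[[5L]], sigma_dc = par[[6L]])
  converged <- best$fit$info %in% 1:4
  # a fitted loss peak far outside the measured window means the spectrum
  # carried no resolvable relaxation (e.g. pure conductivity): flag it
  tau_alpha <- tau_alpha_from_hn(params)
  f_peak <- 1 / (2 * pi * tau_alpha)
  in_window <- f_peak >= min(f) / 10 && f_peak <= max(f) * 10
  if (!in_window) converged <- FALSE
  if (!converged) {
    warning("HN fit did not converge to a loss peak inside the measured window",
            call. = FALSE)
  }
  se <- tryCatch({
    s <- summary(best$fit)$coefficients[, "Std. Error"]
    setNames(as.numeric(s),
             c("eps_inf", "delta_eps", "alpha", "beta", "log10_tau_hn", "sigma_dc"))
  }, error = function(e) NULL)

  diagnostics <- structure(
    list(residual_norm = best$rn, n_restarts_used = n_used,
         converged = converged, stderr = se, info = best$fit$info),
    class = "fit_diagnostics")
  structure(list(parameters = params, tau_alpha = tau_alpha,
                 diagnostics = diagnostics,
                 temperature_K = spectrum$temperature_K),
            class = "hn_fit")
}

#' @export
print.hn_fit <- function(x, ...) {
  cat(sprintf("<hn_fit> T = %.2f K: tau_alpha = %.4g s (converged: %s, resid = %.3g)\n",
              x$temperature_K, x$tau_alpha, x$diagnostics$converged,
              x$diagnostics$residual_norm))
  print(x$parameters)
  invisible(x)
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("<fit_diagnostics> residual norm %.4g, %d restart(s), converged: %s\n",
              x$residual_norm, x$n_restarts_used, x$converged))
  invisible(x)
}
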