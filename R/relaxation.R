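#' Vogel-Fulcher-Tammann parameters
#'
#' Parameters of the VFT law tau(T) = tau0 * exp(D*T0 / (T - T0)): the
#' high-temperature limit tau0 (conventionally 1e-14 s, the quasi-lattice
#' vibration period), the strength parameter D (small D = fragile liquid)
#' and the zero-mobility temperature T0 at which the relaxation time
#' diverges.
#'
#' @param tau0 high-temperature limit relaxation time (s, > 0)
#' @param D dimensionless strength parameter (> 0)
#' @param T0 zero-mobility temperature (K, > 0)
#' @return an object of class `vft_parameters`
#' @export
vft_parameters <- function(tau0, D, T0) {
  assert_that(tau0 > 0, "tau0 must be positive")
  assert_that(D > 0, "D must be positive")
  assert_that(T0 > 0, "T0 must be positive")
  structure(list(tau0 = tau0, D = D, T0 = T0), class = "vft_parameters")
}

#' @export
print.vft_parameters <- function(x, ...) {
  cat(sprintf("<vft_parameters> tau0 = %.4g s, D = %.5g, T0 = %.4f K\n",
              x$tau0, x$D, x$T0))
  invisible(x)
}

#' VFT relaxation time
#'
#' tau(T) = tau0 * exp(D*T0 / (T - T0)); strictly decreasing in T and
#' divergent as T approaches T0 from above.
#'
#' @param temperature_K temperatures (K), all > T0; vectorized
#' @param params a [vft_parameters()] object
#' @return relaxation times in seconds
#' @export
vft_tau <- function(temperature_K, params) {
  stopifnot(inherits(params, "vft_parameters"))
  assert_that(all(temperature_K > params$T0),
              "temperature must exceed T0 (VFT diverges at T0)")
  params$tau0 * exp(params$D * params$T0 / (temperature_K - params$T0))
}

#' Relaxation time series
#'
#' A set of (temperature, relaxation time) points for one process, either
#' the cooperative alpha process or the local (Johari-Goldstein type) beta
#' process.
#'
#' @param temperature_K distinct temperatures (K)
#' @param tau_s relaxation times (s, > 0)
#' @param process `"alpha"` or `"beta"`
#' @return an object of class `relaxation_series`
#' @export
relaxation_series <- function(temperature_K, tau_s, process = c("alpha", "beta")) {
  process <- match.arg(process)
  assert_that(length(temperature_K) == length(tau_s),
              "temperature_K and tau_s must have equal length")
  assert_that(!anyDuplicated(temperature_K), "temperatures must be distinct")
  assert_that(all(tau_s > 0), "relaxation times must be positive")
  assert_that(all(temperature_K > 0), "temperatures must be positive")
  o <- order(temperature_K)
  structure(list(process = process,
                 temperature_K = as.numeric(temperature_K)[o],
                 tau_s = as.numeric(tau_s)[o]),
            class = "relaxation_series")
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf("<relaxation_series> %s process, %d points, T in [%.2f, %.2f] K\n",
              x$process, length(x$temperature_K),
              min(x$temperature_K), max(x$temperature_K)))
  invisible(x)
}

#' Fit the VFT equation to a relaxation time series
#'
#' Nonlinear least squares on log10(tau) (the observable spans many
#' decades, so fitting on the log scale weights all temperatures evenly).
#' With `fix_tau0 = TRUE` (the default) the pre-exponential factor is
#' pinned to 1e-14 s; otherwise log10(tau0) is a free parameter.
#' Multi-start over T0 avoids the shallow local minima of the VFT
#' residual surface.
#'
#' @param series a [relaxation_series()] with at least 4 points
#' @param fix_tau0 pin tau0 to `tau0_fixed`?
#' @param tau0_fixed the pinned pre-exponential factor (s)
#' @return a list of class `vft_fit` with `parameters`
#'   ([vft_parameters()]) and `diagnostics`
#' @export
fit_vft <- function(series, fix_tau0 = TRUE, tau0_fixed = 1e-14) {
  stopifnot(inherits(series, "relaxation_series"))
  temps <- series$temperature_K
  lt_obs <- log10(series$tau_s)
  assert_that(length(temps) >= 4L, "VFT fitting needs at least 4 (T, tau) points")

  model_lt <- function(par) {
    if (fix_tau0) {
      lt0 <- log10(tau0_fixed); D <- par[[1L]]; T0 <- par[[2L]]
    } else {
      lt0 <- par[[1L]]; D <- par[[2L]]; T0 <- par[[3L]]
    }
    lt0 + D * T0 / ((temps - T0) * log(10))
  }
  resid_fun <- function(par) model_lt(par) - lt_obs

  T0_max <- min(temps) - 1e-3
  T0_starts <- c(0.6, 0.75, 0.9) * min(temps)
  best <- NULL
  for (T00 in T0_starts) {
    start <- if (fix_tau0) c(10, T00) else c(-14, 10, T00)
    lower <- if (fix_tau0) c(1e-6, 1) else c(-30, 1e-6, 1)
    upper <- if (fix_tau0) c(1e3, T0_max) else c(0, 1e3, T0_max)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  assert_that(!is.null(best), "VFT fit failed at every restart")
  par <- best$fit$par
  params <- if (fix_tau0) {
    vft_parameters(tau0 = tau0_fixed, D = par[[1L]], T0 = par[[2L]])
  } else {
    vft_parameters(tau0 = 10^par[[1L]], D = par[[2L]], T0 = par[[3L]])
  }
  converged <- best$fit$info %in% 1:4
  if (!converged) warning("VFT fit did not converge", call. = FALSE)
  se <- tryCatch({
    s <- summary(best$fit)$coefficients[, "Std. Error"]
    nm <- if (fix_tau0) c("D", "T0") else c("log10_tau0", "D", "T0")
    setNames(as.numeric(s), nm)
  }, error = function(e) NULL)
  diagnostics <- structure(
    list(residual_norm = best$rn, n_restarts_used = length(T0_starts),
         converged = converged, stderr = se, info = best$fit$info),
    class = "fit_diagnostics")
  structure(list(parameters = params, diagnostics = diagnostics,
                 fix_tau0 = fix_tau0), class = "vft_fit")
}

#' @export
print.vft_fit <- function(x, ...) {
  print(x$parameters)
  print(x$diagnostics)
  invisible(x)
}

#' Operational glass transition temperature
#'
#' The temperature at which the VFT relaxation time reaches a conventional
#' value (100 s by default), in closed form:
#' Tg = T0 * (1 + D / ln(tau_at_Tg / tau0)).
#'
#' @param params a [vft_parameters()] object
#' @param tau_at_Tg the relaxation time defining Tg (s), must exceed tau0
#' @return Tg in kelvin
#' @export
glass_transition_temperature <- function(params, tau_at_Tg = 100) {
  stopifnot(inherits(params, "vft_parameters"))
  assert_that(tau_at_Tg > params$tau0,
              "tau_at_Tg must exceed tau0 for Tg to exist")
  params$T0 * (1 + params$D / log(tau_at_Tg / params$tau0))
}

#' Dynamic fragility index
#'
#' The steepness m = d log10(tau) / d(Tg/T) at T = Tg. For the VFT law
#' this is m = D * (T0/Tg) / ((1 - T0/Tg)^2 * ln 10). Under the
#' conventions tau0 = 1e-14 s and tau(Tg) = 100 s the Arrhenius (strong)
#' limit is m = 16; typical fragile organic liquids exceed 100.
#'
#' @param params a [vft_parameters()] object
#' @param Tg glass transition temperature (K), > T0
#' @return an object of class `fragility_result` with the index `m`, `Tg`
#'   and a classification (`strong` m < 30, `intermediate` 30 <= m < 100,
#'   `fragile` m >= 100)
#' @export
fragility <- function(params, Tg) {
  stopifnot(inherits(params, "vft_parameters"))
  assert_that(Tg > params$T0, "Tg must exceed T0")
  x <- params$T0 / Tg
  m <- params$D * x / ((1 - x)^2 * log(10))
  classification <- if (m < 30) "strong" else if (m < 100) "intermediate" else "fragile"
  structure(list(m = m, Tg = Tg, classification = classification),
            class = "fragility_result")
}

#' @export
print.fragility_result <- function(x, ...) {
  cat(sprintf("<fragility_result> m = %.2f at Tg = %.2f K (%.2f C): %s glass former\n",
              x$m, x$Tg, celsius_from_kelvin(x$Tg), x$classification))
  invisible(x)
}

#' Solve VFT parameters from a target Tg and fragility
#'
#' Inverts the two conventions tau(Tg) = tau_at_Tg and m = fragility at Tg
#' for (D, T0) at fixed tau0. Writing L = log10(tau_at_Tg / tau0), the
#' Arrhenius limit of m is L, and the fragility relation reduces to
#' m = L / (1 - T0/Tg), so T0 = Tg * (1 - L/m) and
#' D = ln(10) * L * (Tg - T0) / T0.
#'
#' @param Tg target glass transition temperature (K)
#' @param m target fragility index (> the Arrhenius limit L)
#' @param tau0 pre-exponential factor (s)
#' @param tau_at_Tg relaxation time at Tg (s)
#' @return a [vft_parameters()] object
#' @export
vft_from_tg_fragility <- function(Tg, m, tau0 = 1e-14, tau_at_Tg = 100) {
  L <- log10(tau_at_Tg / tau0)
  assert_that(L > 0, "tau_at_Tg must exceed tau0")
  assert_that(m > L, sprintf("m must exceed the Arrhenius limit %.3g", L))
  T0 <- Tg * (1 - L / m)
  D <- log(10) * L * (Tg - T0) / T0
  vft_parameters(tau0 = tau0, D = D, T0 = T0)
}

#' Adam-Gibbs-Vogel state
#'
#' VFT parameters plus a fictive temperature T_f describing the frozen
#' configurational state of a glass: T_f = Tg for a freshly quenched
#' glass, T_f = T for a fully equilibrated (infinitely aged) one, in
#' which case the AGV law reduces to VFT.
#'
#' @param vft a [vft_parameters()] object
#' @param T_f fictive temperature (K), > T0
#' @return an object of class `agv_state`
#' @export
agv_state <- function(vft, T_f) {
  stopifnot(inherits(vft, "vft_parameters"))
  assert_that(T_f > vft$T0, "the fictive temperature must exceed T0")
  structure(list(vft = vft, T_f = T_f), class = "agv_state")
}

#' Adam-Gibbs-Vogel relaxation time
#'
#' tau(T) = tau0 * exp(D*T0 / (T * (1 - T0/T_f))). With T_f = T this is
#' the VFT law; with T_f fixed (e.g. at Tg for a fresh glass) the
#' denominator is linear in T, so log10(tau) is exactly linear in 1/T —
#' the glassy branch is Arrhenius with a constant apparent activation
#' energy.
#'
#' @param temperature_K temperatures (K, > 0); vectorized
#' @param state an [agv_state()] object
#' @return relaxation times in seconds
#' @export
agv_tau <- function(temperature_K, state) {
  stopifnot(inherits(state, "agv_state"))
  assert_that(all(temperature_K > 0), "temperature must be positive")
  v <- state$vft
  denom <- temperature_K * (1 - v$T0 / state$T_f)
  assert_that(all(denom > 0), "T * (1 - T0/T_f) must be positive")
  v$tau0 * exp(v$D * v$T0 / denom)
}

#' Arrhenius parameters for the beta relaxation
#'
#' tau_beta(T) = tau_inf * exp(delta_E / (R*T)) with a molar activation
#' energy delta_E (J/mol) and the molar gas constant R. (Stating the
#' barrier per mole and dividing by R is equivalent to a per-molecule
#' barrier over k_B; the molar form matches how such barriers are
#' reported, in kJ/mol.)
#'
#' @param tau_inf pre-exponential factor (s, > 0)
#' @param delta_E molar activation energy (J/mol, >= 0)
#' @return an object of class `arrhenius_parameters`
#' @export
arrhenius_parameters <- function(tau_inf, delta_E) {
  assert_that(tau_inf > 0, "tau_inf must be positive")
  assert_that(delta_E >= 0, "delta_E must be non-negative")
  structure(list(tau_inf = tau_inf, delta_E = delta_E, R = gas_constant),
            class = "arrhenius_parameters")
}

#' @export
print.arrhenius_parameters <- function(x, ...) {
  cat(sprintf("<arrhenius_parameters> tau_inf = %.4g s, delta_E = %.4g kJ/mol\n",
              x$tau_inf, x$delta_E / 1000))
  invisible(x)
}

#' Arrhenius relaxation time
#'
#' @param temperature_K temperatures (K, > 0); vectorized
#' @param params an [arrhenius_parameters()] object
#' @return relaxation times in seconds; log10(tau) is exactly linear in 1/T
#' @export
arrhenius_tau <- function(temperature_K, params) {
  stopifnot(inherits(params, "arrhenius_parameters"))
  assert_that(all(temperature_K > 0), "temperature must be positive")
  params$tau_inf * exp(params$delta_E / (params$R * temperature_K))
}

#' Fit the Arrhenius law to a relaxation series
#'
#' Ordinary least squares of ln(tau) on 1/T: slope = delta_E/R, intercept
#' = ln(tau_inf).
#'
#' @param series a [relaxation_series()] with at least 3 points
#' @return a list of class `arrhenius_fit` with `parameters`
#'   ([arrhenius_parameters()]) and `diagnostics` (stderr of the molar
#'   activation energy, R^2)
#' @export
fit_arrhenius <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  assert_that(length(series$temperature_K) >= 3L,
              "Arrhenius fitting needs at least 3 points")
  x <- 1 / series$temperature_K
  y <- log(series$tau_s)
  fit <- lm(y ~ x)
  co <- coef(fit)
  params <- arrhenius_parameters(tau_inf = exp(co[[1L]]),
                                 delta_E = co[[2L]] * gas_constant)
  sm <- suppressWarnings(summary(fit))
  diagnostics <- structure(
    list(residual_norm = sqrt(sum(fit$residuals^2)), n_restarts_used = 1L,
         converged = TRUE,
         stderr = c(delta_E = sm$coefficients[2L, 2L] * gas_constant),
         r_squared = sm$r.squared),
    class = "fit_diagnostics")
  structure(list(parameters = params, diagnostics = diagnostics),
            class = "arrhenius_fit")
}
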