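#' Decoupling exponent between growth kinetics and a mobility measure
#'
#' Log-log regression of a response (e.g. the kinetic growth rate u_kin,
#' or the layer time tau_u) on a mobility predictor (viscosity eta,
#' relaxation time tau_alpha or tau_beta, or diffusivity D_bulk):
#' log10(response) = slope * log10(predictor) + A. The decoupling
#' exponent xi is reported as the magnitude of the slope; the fitted
#' slope sign is kept alongside (negative for u_kin against eta or
#' tau_alpha, positive for u_kin against D_bulk and for tau_u against
#' tau_beta). xi = 1 means full Stokes-Einstein-type coupling; xi < 1
#' means the kinetics are enhanced relative to the mobility measure.
#'
#' Temperature matching is an exact-key join (after conversion to K);
#' no interpolation is performed, because interpolating log(tau) near Tg
#' would dominate the fit.
#'
#' @param predictor,response data.frames (or lists) with numeric fields
#'   `temperature_K` and `value`; all values must be positive
#' @param pair_label length-2 character vector `c(response, predictor)`,
#'   e.g. `c("u_kin", "tau_alpha")`
#' @param method `"ols"` (ordinary least squares on the log10 values) or
#'   `"deming"` (errors in both variables, error-variance ratio 1)
#' @param fit_window optional `c(Tmin_K, Tmax_K)` restricting the shared
#'   temperatures used in the fit
#' @return an object of class `coupling_fit` with fields `xi`, `slope`,
#'   `intercept`, `stderr_xi`, `r_squared`, `n_points`, `pair_label`,
#'   `method`
#' @export
decoupling_exponent <- function(predictor, response,
                                pair_label = c("response", "predictor"),
                                method = c("ols", "deming"),
                                fit_window = NULL) {
  method <- match.arg(method)
  assert_that(length(pair_label) == 2L, "pair_label must have length 2")
  joined <- join_on_temperature(predictor, response)
  if (!is.null(fit_window)) {
    keep <- joined$temperature_K >= fit_window[[1L]] &
      joined$temperature_K <= fit_window[[2L]]
    joined <- joined[keep, , drop = FALSE]
  }
  assert_that(nrow(joined) >= 3L,
              "the two series must share at least 3 temperatures")
  assert_that(all(joined$x > 0) && all(joined$y > 0),
              "all values must be positive (log-log regression)")
  lx <- log10(joined$x)
  ly <- log10(joined$y)

  if (method == "ols") {
    fit <- lm(ly ~ lx)
    slope <- coef(fit)[[2L]]
    intercept <- coef(fit)[[1L]]
    # summary.lm warns on exact fits; zero residual variance is fine here
    sm <- suppressWarnings(summary(fit))
    stderr_xi <- sm$coefficients[2L, 2L]
    r_squared <- sm$r.squared
    # a constant response has zero slope variance; lm reports R^2 = NaN there
    if (!is.finite(r_squared)) r_squared <- if (var(ly) == 0) 1 else 0
    if (!is.finite(stderr_xi)) stderr_xi <- 0
  } else {
    dem <- deming_slope(lx, ly)
    slope <- dem$slope
    intercept <- dem$intercept
    stderr_xi <- dem$stderr
    r_squared <- if (var(ly) == 0) 1 else stats::cor(lx, ly)^2
  }

  structure(list(xi = abs(slope), slope = slope, intercept = intercept,
                 stderr_xi = stderr_xi, r_squared = r_squared,
                 n_points = nrow(joined),
                 pair_label = as.character(pair_label), method = method),
            class = "coupling_fit")
}

# exact-key join of two (temperature_K, value) tables; keys rounded to
# micro-kelvin so 25 + 273.15 matched from different files cannot miss
join_on_temperature <- function(predictor, response) {
  px <- round(predictor$temperature_K, 6)
  rx <- round(response$temperature_K, 6)
  shared <- intersect(px, rx)
  data.frame(temperature_K = shared,
             x = predictor$value[match(shared, px)],
             y = response$value[match(shared, rx)])
}

# Deming regression with error-variance ratio 1; jackknife standard error
deming_slope <- function(x, y) {
  n <- length(x)
  one <- function(x, y) {
    sxx <- var(x); syy <- var(y); sxy <- stats::cov(x, y)
    if (sxy == 0) return(list(slope = 0, intercept = mean(y)))
    s <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    list(slope = s, intercept = mean(y) - s * mean(x))
  }
  full <- one(x, y)
  jack <- vapply(seq_len(n), function(i) one(x[-i], y[-i])$slope, numeric(1))
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  list(slope = full$slope, intercept = full$intercept, stderr = se)
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> %s vs %s: xi = %.4g (slope %+.4g, se %.2g), R^2 = %.4f, n = %d [%s]\n",
              x$pair_label[[1L]], x$pair_label[[2L]], x$xi, x$slope,
              x$stderr_xi, x$r_squared, x$n_points, x$method))
  invisible(x)
}

#' Fragility-based prediction of the decoupling exponent
#'
#' The empirical linear correlation between the decoupling exponent of
#' supercooled-liquid crystal growth kinetics and the dynamic fragility:
#' xi_predicted = 1.1 - 0.005 * m. May be negative for extremely fragile
#' liquids; returned as-is.
#'
#' @param m fragility index (> 0); vectorized
#' @return predicted exponent
#' @export
ediger_predicted_xi <- function(m) {
  assert_that(all(m > 0), "m must be positive")
  1.1 - 0.005 * m
}

#' Compare an observed decoupling exponent with the fragility prediction
#'
#' @param fit a [decoupling_exponent()] result whose response is the
#'   kinetic growth rate (`u_kin`); the fragility correlation applies to
#'   supercooled-liquid growth kinetics only, so layer-time/beta pairs
#'   are rejected
#' @param frag a [fragility()] result
#' @return an object of class `ediger_comparison` with `m`,
#'   `xi_observed`, `xi_predicted` and `residual` (observed - predicted)
#' @export
compare_to_ediger <- function(fit, frag) {
  stopifnot(inherits(fit, "coupling_fit"), inherits(frag, "fragility_result"))
  assert_that(fit$pair_label[[1L]] == "u_kin",
              "the fragility correlation applies only to u_kin-type coupling fits")
  xi_pred <- ediger_predicted_xi(frag$m)
  structure(list(m = frag$m, xi_observed = fit$xi, xi_predicted = xi_pred,
                 residual = fit$xi - xi_pred,
                 pair_label = fit$pair_label),
            class = "ediger_comparison")
}

#' @export
print.ediger_comparison <- function(x, ...) {
  cat(sprintf("<ediger_comparison> m = %.2f: xi observed %.3f vs predicted %.3f (residual %+.3f)\n",
              x$m, x$xi_observed, x$xi_predicted, x$residual))
  invisible(x)
}

#' Interpret a coupling exponent
#'
#' Classifies the strength of the coupling between a kinetic observable
#' and a mobility measure: exponents near one (within [0.9, 1.1]) mean
#' the mobility measure controls the kinetics ("coupled"); smaller
#' positive exponents mean partial decoupling; exponents above 1.1 mean
#' the activation energy of the kinetics exceeds that of the relaxation,
#' so the relaxation cannot be triggering the process ("not controlling").
#'
#' @param fit a [decoupling_exponent()] result, or a bare numeric exponent
#' @return one of `"coupled"`, `"partially decoupled"`, `"not controlling"`
#' @export
coupling_coefficient_interpretation <- function(fit) {
  xi <- if (inherits(fit, "coupling_fit")) fit$xi else fit
  assert_that(is.numeric(xi) && length(xi) == 1L && is.finite(xi) && xi >= 0,
              "xi must be a single non-negative number")
  if (xi > 1.1) "not controlling"
  else if (xi >= 0.9) "coupled"
  else "partially decoupled"
}
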