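#' Shear viscosity series
#'
#' Steady shear viscosity measurements eta(T); like the relaxation time,
#' viscosity is super-Arrhenius in a fragile liquid and spans several
#' orders of magnitude over a few tens of kelvin above Tg.
#'
#' @param temperature_K distinct temperatures (K)
#' @param eta_Pa_s viscosities (Pa s, > 0)
#' @return an object of class `viscosity_series`
#' @export
viscosity_series <- function(temperature_K, eta_Pa_s) {
  assert_that(length(temperature_K) == length(eta_Pa_s),
              "temperature_K and eta_Pa_s must have equal length")
  assert_that(!anyDuplicated(temperature_K), "temperatures must be distinct")
  assert_that(all(eta_Pa_s > 0), "viscosities must be positive")
  o <- order(temperature_K)
  structure(list(temperature_K = as.numeric(temperature_K)[o],
                 eta_Pa_s = as.numeric(eta_Pa_s)[o]),
            class = "viscosity_series")
}

#' @export
print.viscosity_series <- function(x, ...) {
  cat(sprintf("<viscosity_series> %d points, T in [%.2f, %.2f] K, eta in [%.3g, %.3g] Pa s\n",
              length(x$temperature_K), min(x$temperature_K), max(x$temperature_K),
              min(x$eta_Pa_s), max(x$eta_Pa_s)))
  invisible(x)
}
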