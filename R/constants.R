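#' Physical constants and temperature conversion
#'
#' CODATA values used throughout: the vacuum permittivity (F/m) in the
#' dc-conductivity term of the dielectric model, and the molar gas constant
#' (J/(mol K)) in the driving-force factor and the Arrhenius law.
#'
#' @name constants
NULL

#' @rdname constants
#' @export
eps0_vacuum <- 8.8541878128e-12

#' @rdname constants
#' @export
gas_constant <- 8.314462618

#' @param temperature_C temperature in degrees Celsius
#' @rdname constants
#' @export
kelvin_from_celsius <- function(temperature_C) temperature_C + 273.15

#' @param temperature_K temperature in kelvin
#' @rdname constants
#' @export
celsius_from_kelvin <- function(temperature_K) temperature_K - 273.15

# internal: stop() with caller-friendly message when a condition fails
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
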