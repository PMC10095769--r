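#' Melting thermodynamics
#'
#' Melting point and melt-crystal entropy difference used in the
#' thermodynamic driving-force factor. Either `delta_Sm` is supplied
#' directly (J/(mol K), evaluated at Tm) or it is derived from the molar
#' enthalpy of melting as delta_Hm / Tm; when both are given they must be
#' consistent.
#'
#' @param Tm melting temperature (K, > 0)
#' @param delta_Hm molar enthalpy of melting (J/mol), optional
#' @param delta_Sm molar entropy of melting (J/(mol K)), optional
#' @return an object of class `melting_thermo`
#' @export
melting_thermo <- function(Tm, delta_Hm = NULL, delta_Sm = NULL) {
  assert_that(Tm > 0, "Tm must be positive")
  assert_that(!is.null(delta_Hm) || !is.null(delta_Sm),
              "supply delta_Hm or delta_Sm")
  if (is.null(delta_Sm)) delta_Sm <- delta_Hm / Tm
  if (!is.null(delta_Hm)) {
    assert_that(abs(delta_Sm - delta_Hm / Tm) <= 1e-9 * abs(delta_Sm),
                "delta_Sm and delta_Hm/Tm disagree")
  }
  assert_that(delta_Sm > 0, "delta_Sm must be positive")
  structure(list(Tm = Tm, delta_Hm = delta_Hm, delta_Sm = delta_Sm,
                 R = gas_constant),
            class = "melting_thermo")
}

#' @export
print.melting_thermo <- function(x, ...) {
  cat(sprintf("<melting_thermo> Tm = %.2f K (%.2f C), delta_Sm = %.4g J/(mol K)\n",
              x$Tm, celsius_from_kelvin(x$Tm), x$delta_Sm))
  invisible(x)
}

#' Crystal growth rate series
#'
#' Measured growth-front velocities u(T) for one growth environment.
#' Bulk and surface series are kept separate and never pooled: surface
#' growth has its own mechanism (surface diffusion, disrupted by liquid
#' flow above Tg) and is excluded from the driving-force analysis.
#'
#' @param temperature_K distinct temperatures (K)
#' @param u_m_per_s growth rates (m/s, > 0)
#' @param environment `"bulk"` or `"surface"`
#' @param u_se optional per-point uncertainties (m/s)
#' @return an object of class `growth_rate_series`
#' @export
growth_rate_series <- function(temperature_K, u_m_per_s,
                               environment = c("bulk", "surface"),
                               u_se = NULL) {
  environment <- match.arg(environment)
  assert_that(length(temperature_K) == length(u_m_per_s),
              "temperature_K and u_m_per_s must have equal length")
  assert_that(!anyDuplicated(temperature_K), "temperatures must be distinct")
  assert_that(all(u_m_per_s > 0), "growth rates must be positive")
  o <- order(temperature_K)
  structure(list(environment = environment,
                 temperature_K = as.numeric(temperature_K)[o],
                 u_m_per_s = as.numeric(u_m_per_s)[o],
                 u_se = if (!is.null(u_se)) as.numeric(u_se)[o]),
            class = "growth_rate_series")
}

#' @export
print.growth_rate_series <- function(x, ...) {
  cat(sprintf("<growth_rate_series> %s, %d points, T in [%.2f, %.2f] K, u in [%.3g, %.3g] m/s\n",
              x$environment, length(x$temperature_K),
              min(x$temperature_K), max(x$temperature_K),
              min(x$u_m_per_s), max(x$u_m_per_s)))
  invisible(x)
}

#' Kinetic part of the crystal growth rate
#'
#' Divides the measured growth rate by the thermodynamic driving-force
#' factor 1 - exp(-delta_Sm * (Tm - T) / (R*T)), isolating the
#' mobility-limited kinetics: u_kin = u / factor. At deep undercooling the
#' factor approaches 1 and u_kin approaches u; near Tm the factor
#' vanishes, so a warning is emitted when it drops below 0.05 (the
#' division then amplifies measurement noise).
#'
#' @param u measured growth rate (m/s, > 0); vectorized with `temperature_K`
#' @param temperature_K temperatures (K), all strictly below Tm
#' @param thermo a [melting_thermo()] object
#' @return a list with `u_kin` (m/s) and `factor` (dimensionless in (0, 1))
#' @export
kinetic_growth_rate <- function(u, temperature_K, thermo) {
  stopifnot(inherits(thermo, "melting_thermo"))
  assert_that(all(u > 0), "growth rates must be positive")
  assert_that(all(temperature_K > 0), "temperature must be positive")
  assert_that(all(temperature_K < thermo$Tm),
              "temperature must be below Tm (no driving force at or above Tm)")
  factor <- 1 - exp(-thermo$delta_Sm * (thermo$Tm - temperature_K) /
                      (thermo$R * temperature_K))
  if (any(factor < 0.05)) {
    warning("driving-force factor below 0.05 near Tm: u_kin is noise-amplified",
            call. = FALSE)
  }
  list(u_kin = u / factor, factor = factor)
}

#' Kinetic growth series
#'
#' Applies [kinetic_growth_rate()] to every point of a bulk
#' [growth_rate_series()].
#'
#' @param series a bulk [growth_rate_series()]
#' @param thermo a [melting_thermo()] object
#' @return an object of class `kinetic_growth_series` with parallel
#'   vectors `temperature_K`, `u_kin_m_per_s`, `driving_force_factor`
#' @export
kinetic_growth_series <- function(series, thermo) {
  stopifnot(inherits(series, "growth_rate_series"))
  k <- kinetic_growth_rate(series$u_m_per_s, series$temperature_K, thermo)
  structure(list(environment = series$environment,
                 temperature_K = series$temperature_K,
                 u_m_per_s = series$u_m_per_s,
                 u_kin_m_per_s = k$u_kin,
                 driving_force_factor = k$factor),
            class = "kinetic_growth_series")
}

#' @export
print.kinetic_growth_series <- function(x, ...) {
  cat(sprintf("<kinetic_growth_series> %d points, driving-force factor in [%.3g, %.3g]\n",
              length(x$temperature_K),
              min(x$driving_force_factor), max(x$driving_force_factor)))
  invisible(x)
}

#' Molecular diameter from the volume per molecule
#'
#' Treats the molecules as spheres packed to fill 74% of space (close
#' packing): d = 1.12 * V^(1/3), with V the unit-cell volume per molecule
#' in cubic angstroms and d in angstroms. The diameter doubles when V is
#' multiplied by 8.
#'
#' @param V_A3 volume per molecule (cubic angstrom, > 0); vectorized
#' @return diameter in angstroms
#' @export
molecular_diameter <- function(V_A3) {
  assert_that(all(V_A3 > 0), "V must be positive")
  1.12 * V_A3^(1 / 3)
}

#' Molecular geometry
#'
#' Carries the molecular diameter d (angstrom), which also serves as the
#' crystal layer thickness. Supply exactly one of the per-molecule volume
#' V (d is derived via [molecular_diameter()]) or d directly.
#'
#' @param V_A3 volume per molecule (cubic angstrom), optional
#' @param d_A molecular diameter (angstrom), optional
#' @return an object of class `molecular_geometry`
#' @export
molecular_geometry <- function(V_A3 = NULL, d_A = NULL) {
  assert_that(xor(is.null(V_A3), is.null(d_A)),
              "supply exactly one of V_A3 or d_A")
  if (is.null(d_A)) d_A <- molecular_diameter(V_A3)
  assert_that(d_A > 0, "d must be positive")
  structure(list(V_A3 = V_A3, d_A = d_A), class = "molecular_geometry")
}

#' @export
print.molecular_geometry <- function(x, ...) {
  cat(sprintf("<molecular_geometry> d = %.3g angstrom%s\n", x$d_A,
              if (!is.null(x$V_A3)) sprintf(" (from V = %.4g A^3)", x$V_A3) else ""))
  invisible(x)
}

#' Predicted bulk diffusivity
#'
#' Hopping diffusivity of a bulk homogeneous material from the structural
#' relaxation time: D_bulk = d^2 / (6 * tau_alpha), with the molecular
#' diameter d as the elementary jump length.
#'
#' @param d molecular diameter, in angstroms by default
#' @param tau_alpha structural relaxation time (s, > 0); vectorized
#' @param d_unit `"angstrom"` (converted to metres internally) or `"m"`
#' @return diffusivity in m^2/s
#' @export
bulk_diffusivity <- function(d, tau_alpha, d_unit = c("angstrom", "m")) {
  d_unit <- match.arg(d_unit)
  assert_that(all(d > 0), "d must be positive")
  assert_that(all(tau_alpha > 0), "tau_alpha must be positive")
  d_m <- if (d_unit == "angstrom") d * 1e-10 else d
  d_m^2 / (6 * tau_alpha)
}

#' Crystal layer time
#'
#' The time tau_u = d / u for the crystal front to advance one molecular
#' layer of thickness d at growth rate u.
#'
#' @param u growth rate (m/s, > 0); vectorized
#' @param d layer thickness (molecular diameter), in angstroms by default
#' @param d_unit `"angstrom"` or `"m"`
#' @return layer time in seconds
#' @export
layer_time <- function(u, d, d_unit = c("angstrom", "m")) {
  d_unit <- match.arg(d_unit)
  assert_that(all(u > 0), "u must be positive")
  assert_that(all(d > 0), "d must be positive")
  d_m <- if (d_unit == "angstrom") d * 1e-10 else d
  d_m / u
}

#' Layers grown per structural relaxation time
#'
#' The ratio tau_alpha / tau_u: how many molecular layers the crystal
#' adds while the liquid (or glass) completes one structural relaxation.
#' Values well above 1 — tens of layers per relaxation — flag growth that
#' has decoupled from bulk structural relaxation (glass-to-crystal mode).
#'
#' @param tau_alpha structural relaxation time (s, > 0)
#' @param tau_u layer time (s, > 0)
#' @return dimensionless layer count; vectorized
#' @export
layers_per_alpha_time <- function(tau_alpha, tau_u) {
  assert_that(all(tau_alpha > 0), "tau_alpha must be positive")
  assert_that(all(tau_u > 0), "tau_u must be positive")
  tau_alpha / tau_u
}
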