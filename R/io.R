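# CSV dialects. User-facing files use laboratory units — temperatures in
# degrees Celsius, growth rates in micrometres per second, diameters in
# angstroms — and are converted to SI/kelvin at ingestion.

#' Read and write dielectric spectra CSV
#'
#' Columns `temperature_C`, `frequency_Hz`, `eps_real`, `eps_imag`; one
#' block of rows per temperature.
#'
#' @param spectra list of [dielectric_spectrum()] objects
#' @param path file path
#' @return `read_spectra_csv()` returns a list of [dielectric_spectrum()]
#' @export
write_spectra_csv <- function(spectra, path) {
  rows <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(temperature_C = celsius_from_kelvin(s$temperature_K),
               frequency_Hz = s$frequency_Hz,
               eps_real = s$eps_real, eps_imag = s$eps_imag)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  d <- read.csv(path)
  need <- c("temperature_C", "frequency_Hz", "eps_real", "eps_imag")
  assert_that(all(need %in% names(d)),
              paste("spectra CSV must have columns", paste(need, collapse = ", ")))
  lapply(split(d, d$temperature_C), function(b) {
    b <- b[order(b$frequency_Hz), ]
    dielectric_spectrum(kelvin_from_celsius(b$temperature_C[[1L]]),
                        b$frequency_Hz, b$eps_real, b$eps_imag)
  })
}

#' Read and write relaxation time CSV
#'
#' Columns `temperature_C`, `tau_s`, `process` (`alpha` or `beta`).
#'
#' @param series a [relaxation_series()]
#' @param path file path
#' @param process which process to extract on read
#' @return `read_relaxation_csv()` returns a [relaxation_series()]
#' @export
write_relaxation_csv <- function(series, path) {
  d <- data.frame(temperature_C = celsius_from_kelvin(series$temperature_K),
                  tau_s = series$tau_s, process = series$process)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relaxation_csv
#' @export
read_relaxation_csv <- function(path, process = c("alpha", "beta")) {
  process <- match.arg(process)
  d <- read.csv(path)
  need <- c("temperature_C", "tau_s", "process")
  assert_that(all(need %in% names(d)),
              paste("relaxation CSV must have columns", paste(need, collapse = ", ")))
  d <- d[d$process == process, ]
  assert_that(nrow(d) > 0, sprintf("no '%s' rows in %s", process, path))
  relaxation_series(kelvin_from_celsius(d$temperature_C), d$tau_s, process)
}

#' Read and write viscosity CSV
#'
#' Columns `temperature_C`, `eta_Pa_s`.
#'
#' @param series a [viscosity_series()]
#' @param path file path
#' @return `read_viscosity_csv()` returns a [viscosity_series()]
#' @export
write_viscosity_csv <- function(series, path) {
  d <- data.frame(temperature_C = celsius_from_kelvin(series$temperature_K),
                  eta_Pa_s = series$eta_Pa_s)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_viscosity_csv
#' @export
read_viscosity_csv <- function(path) {
  d <- read.csv(path)
  need <- c("temperature_C", "eta_Pa_s")
  assert_that(all(need %in% names(d)),
              paste("viscosity CSV must have columns", paste(need, collapse = ", ")))
  viscosity_series(kelvin_from_celsius(d$temperature_C), d$eta_Pa_s)
}

#' Read and write crystal growth rate CSV
#'
#' Columns `temperature_C`, `u_um_per_s` (micrometres per second, the
#' microscopy convention), `environment` (`bulk` or `surface`).
#'
#' @param series a [growth_rate_series()]
#' @param path file path
#' @param environment which environment to extract on read
#' @return `read_growth_csv()` returns a [growth_rate_series()]
#' @export
write_growth_csv <- function(series, path) {
  d <- data.frame(temperature_C = celsius_from_kelvin(series$temperature_K),
                  u_um_per_s = series$u_m_per_s * 1e6,
                  environment = series$environment)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path, environment = c("bulk", "surface")) {
  environment <- match.arg(environment)
  d <- read.csv(path)
  need <- c("temperature_C", "u_um_per_s", "environment")
  assert_that(all(need %in% names(d)),
              paste("growth CSV must have columns", paste(need, collapse = ", ")))
  d <- d[d$environment == environment, ]
  assert_that(nrow(d) > 0, sprintf("no '%s' rows in %s", environment, path))
  growth_rate_series(kelvin_from_celsius(d$temperature_C),
                     d$u_um_per_s * 1e-6, environment)
}
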