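#' Study configuration for the end-to-end pipeline
#'
#' Paths to the measurement files plus the material constants the
#' analysis needs. Any file path may be `NULL`; the pipeline skips the
#' stages that depend on it and records the skip. Alpha-relaxation times
#' come either from raw dielectric spectra (`spectra_csv`, fitted per
#' temperature) or precomputed (`tau_alpha_csv`); beta-relaxation
#' Arrhenius parameters come either from a measured series
#' (`tau_beta_csv`, fitted) or directly via `beta_arrhenius`.
#'
#' @param spectra_csv dielectric spectra file (see [read_spectra_csv()])
#' @param tau_alpha_csv precomputed alpha relaxation times
#' @param viscosity_csv shear viscosity file
#' @param growth_csv supercooled-liquid bulk growth rates
#' @param glassy_growth_csv glassy-state bulk growth rates
#' @param tau_beta_csv measured beta relaxation times
#' @param melting a [melting_thermo()] (required for the kinetic part)
#' @param geometry a [molecular_geometry()] (exactly one of V or d)
#' @param beta_arrhenius optional [arrhenius_parameters()] used when no
#'   `tau_beta_csv` is given
#' @param Tg_override_K optional calorimetric Tg overriding the
#'   relaxation-time convention
#' @param tau_at_Tg Tg convention: tau_alpha(Tg) in seconds
#' @param fix_tau0 pin the VFT pre-exponential to `tau0_fixed`?
#' @param tau0_fixed pinned VFT tau0 (s)
#' @param hn_options an [hn_fit_options()] list
#' @param fit_window_C optional `c(Tmin_C, Tmax_C)` restricting coupling
#'   fits to an intermediate/deep supercooled window
#' @param coupling_method `"ols"` or `"deming"`
#' @param seed integer seed recorded in provenance
#' @return an object of class `study_config`
#' @export
study_config <- function(spectra_csv = NULL, tau_alpha_csv = NULL,
                         viscosity_csv = NULL, growth_csv = NULL,
                         glassy_growth_csv = NULL, tau_beta_csv = NULL,
                         melting = NULL, geometry = NULL,
                         beta_arrhenius = NULL, Tg_override_K = NULL,
                         tau_at_Tg = 100, fix_tau0 = TRUE, tau0_fixed = 1e-14,
                         hn_options = hn_fit_options(), fit_window_C = NULL,
                         coupling_method = c("ols", "deming"), seed = 1L) {
  coupling_method <- match.arg(coupling_method)
  for (p in c(spectra_csv, tau_alpha_csv, viscosity_csv, growth_csv,
              glassy_growth_csv, tau_beta_csv)) {
    assert_that(file.exists(p), sprintf("input file not found: %s", p))
  }
  if (!is.null(melting)) stopifnot(inherits(melting, "melting_thermo"))
  if (!is.null(geometry)) stopifnot(inherits(geometry, "molecular_geometry"))
  if (!is.null(beta_arrhenius)) stopifnot(inherits(beta_arrhenius, "arrhenius_parameters"))
  assert_that(tau_at_Tg > 0, "tau_at_Tg must be positive")
  structure(
    list(spectra_csv = spectra_csv, tau_alpha_csv = tau_alpha_csv,
         viscosity_csv = viscosity_csv, growth_csv = growth_csv,
         glassy_growth_csv = glassy_growth_csv, tau_beta_csv = tau_beta_csv,
         melting = melting, geometry = geometry,
         beta_arrhenius = beta_arrhenius, Tg_override_K = Tg_override_K,
         tau_at_Tg = tau_at_Tg, fix_tau0 = fix_tau0, tau0_fixed = tau0_fixed,
         hn_options = hn_options, fit_window_C = fit_window_C,
         coupling_method = coupling_method, seed = as.integer(seed)),
    class = "study_config")
}

#' Serialize and restore a study configuration
#'
#' JSON round-trip of a [study_config()]. Relative file paths are kept
#' as written.
#'
#' @param config a [study_config()]
#' @param path JSON file path
#' @return `read_study_config()` returns a [study_config()]
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$melting <- if (!is.null(x$melting)) unclass(x$melting)[c("Tm", "delta_Sm")]
  x$geometry <- if (!is.null(x$geometry)) {
    g <- unclass(x$geometry)
    if (!is.null(g$V_A3)) list(V_A3 = g$V_A3) else list(d_A = g$d_A)
  }
  x$beta_arrhenius <- if (!is.null(x$beta_arrhenius)) {
    unclass(x$beta_arrhenius)[c("tau_inf", "delta_E")]
  }
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grab <- function(nm) if (!is.null(x[[nm]])) x[[nm]]
  study_config(
    spectra_csv = grab("spectra_csv"), tau_alpha_csv = grab("tau_alpha_csv"),
    viscosity_csv = grab("viscosity_csv"), growth_csv = grab("growth_csv"),
    glassy_growth_csv = grab("glassy_growth_csv"),
    tau_beta_csv = grab("tau_beta_csv"),
    melting = if (!is.null(x$melting)) {
      melting_thermo(Tm = x$melting$Tm, delta_Sm = x$melting$delta_Sm)
    },
    geometry = if (!is.null(x$geometry)) {
      molecular_geometry(V_A3 = x$geometry$V_A3, d_A = x$geometry$d_A)
    },
    beta_arrhenius = if (!is.null(x$beta_arrhenius)) {
      arrhenius_parameters(x$beta_arrhenius$tau_inf, x$beta_arrhenius$delta_E)
    },
    Tg_override_K = grab("Tg_override_K"),
    tau_at_Tg = x$tau_at_Tg %||% 100,
    fix_tau0 = x$fix_tau0 %||% TRUE,
    tau0_fixed = x$tau0_fixed %||% 1e-14,
    hn_options = if (!is.null(x$hn_options)) {
      do.call(hn_fit_options, x$hn_options)
    } else hn_fit_options(),
    fit_window_C = grab("fit_window_C"),
    coupling_method = x$coupling_method %||% "ols",
    seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest the measurement files; fit the HN model to
#' every spectrum and convert to alpha-relaxation times; fit the VFT
#' equation; locate the operational Tg and the fragility index; divide
#' measured growth rates by the driving-force factor; predict bulk
#' diffusivities; fit the decoupling exponents of u_kin against
#' viscosity, tau_alpha and D_bulk; compare the tau_alpha exponent with
#' the fragility-based prediction; obtain beta-relaxation Arrhenius
#' parameters; fit the glassy-state layer-time/beta-relaxation coupling;
#' and tabulate the glassy-state comparison of layer times with the
#' Adam-Gibbs-Vogel relaxation times of fresh and fully equilibrated
#' glass. Stages whose inputs are missing are skipped and recorded;
#' stage failures are recorded with the stage name and do not abort the
#' run.
#'
#' @param config a [study_config()]
#' @param verbose print one structured log line per stage?
#' @return an object of class `study_report`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  stages <- list()
  note <- function(stage, status, msg = "") {
    stages[[stage]] <<- list(status = status, message = msg)
    if (verbose) message(sprintf("[%s] %s %s", stage, status, msg))
  }
  run_stage <- function(stage, can_run, expr) {
    if (!can_run) {
      note(stage, "skipped", "inputs unavailable")
      return(NULL)
    }
    tryCatch({
      out <- force(expr)
      note(stage, "ok")
      out
    }, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }

  report <- list()

  # -- alpha relaxation times -------------------------------------------
  hn_table <- NULL
  tau_alpha_series <- NULL
  if (!is.null(config$spectra_csv)) {
    hn_res <- run_stage("fit_hn", TRUE, {
      spectra <- read_spectra_csv(config$spectra_csv)
      fits <- lapply(spectra, fit_hn, options = config$hn_options)
      tab <- do.call(rbind, lapply(fits, function(ft) {
        p <- ft$parameters
        data.frame(temperature_C = celsius_from_kelvin(ft$temperature_K),
                   eps_inf = p$eps_inf, eps_s = p$eps_s, alpha = p$alpha,
                   beta = p$beta, tau_hn_s = p$tau_hn, sigma_dc = p$sigma_dc,
                   tau_alpha_s = ft$tau_alpha,
                   converged = ft$diagnostics$converged,
                   residual_norm = ft$diagnostics$residual_norm)
      }))
      rownames(tab) <- NULL
      ok <- tab$converged
      assert_that(sum(ok) >= 4L, "fewer than 4 converged HN fits")
      list(table = tab,
           series = relaxation_series(
             kelvin_from_celsius(tab$temperature_C[ok]),
             tab$tau_alpha_s[ok], "alpha"))
    })
    if (!is.null(hn_res)) {
      hn_table <- hn_res$table
      tau_alpha_series <- hn_res$series
    }
  } else if (!is.null(config$tau_alpha_csv)) {
    tau_alpha_series <- run_stage("read_tau_alpha", TRUE,
                                  read_relaxation_csv(config$tau_alpha_csv, "alpha"))
    note("fit_hn", "skipped", "precomputed relaxation times supplied")
  } else {
    note("fit_hn", "skipped", "inputs unavailable")
  }
  report$hn_fits <- hn_table

  # -- VFT, Tg, fragility -----------------------------------------------
  vft_fit <- run_stage("fit_vft", !is.null(tau_alpha_series),
                       fit_vft(tau_alpha_series, fix_tau0 = config$fix_tau0,
                               tau0_fixed = config$tau0_fixed))
  vft <- if (!is.null(vft_fit)) vft_fit$parameters
  Tg_K <- NULL
  frag <- NULL
  if (!is.null(vft)) {
    Tg_K <- config$Tg_override_K %||%
      glass_transition_temperature(vft, config$tau_at_Tg)
    frag <- run_stage("fragility", TRUE, fragility(vft, Tg_K))
  } else {
    note("fragility", "skipped", "no VFT parameters")
  }
  report$vft <- if (!is.null(vft)) {
    list(tau0_s = vft$tau0, D = vft$D, T0_K = vft$T0,
         stderr = as.list(vft_fit$diagnostics$stderr),
         fix_tau0 = config$fix_tau0)
  }
  report$Tg_K <- Tg_K
  report$Tg_C <- if (!is.null(Tg_K)) celsius_from_kelvin(Tg_K)
  report$fragility <- if (!is.null(frag)) {
    list(m = frag$m, classification = frag$classification)
  }

  # -- kinetic part of growth, predicted diffusivity --------------------
  kinetics <- run_stage("kinetics",
                        !is.null(config$growth_csv) && !is.null(config$melting), {
    growth <- read_growth_csv(config$growth_csv, "bulk")
    ks <- kinetic_growth_series(growth, config$melting)
    tab <- data.frame(temperature_C = celsius_from_kelvin(ks$temperature_K),
                      u_m_per_s = ks$u_m_per_s,
                      driving_force_factor = ks$driving_force_factor,
                      u_kin_m_per_s = ks$u_kin_m_per_s)
    if (!is.null(vft) && !is.null(config$geometry)) {
      # relaxation times on the growth grid come from the fitted VFT law,
      # extended over the full growth-temperature range
      tab$tau_alpha_s <- vft_tau(ks$temperature_K, vft)
      tab$D_bulk_m2_per_s <- bulk_diffusivity(config$geometry$d_A, tab$tau_alpha_s)
    }
    tab
  })
  report$kinetics <- kinetics
  report$molecular_diameter_A <- if (!is.null(config$geometry)) config$geometry$d_A

  # -- coupling fits in the supercooled liquid --------------------------
  window_K <- if (!is.null(config$fit_window_C)) {
    kelvin_from_celsius(sort(config$fit_window_C))
  }
  coupling <- list()
  if (!is.null(kinetics)) {
    u_kin_tab <- list(temperature_K = kelvin_from_celsius(kinetics$temperature_C),
                      value = kinetics$u_kin_m_per_s)
    eta_series <- run_stage("read_viscosity", !is.null(config$viscosity_csv),
                            read_viscosity_csv(config$viscosity_csv))
    if (!is.null(eta_series)) {
      coupling$u_kin_vs_eta <- run_stage("coupling_eta", TRUE,
        decoupling_exponent(
          list(temperature_K = eta_series$temperature_K,
               value = eta_series$eta_Pa_s),
          u_kin_tab, pair_label = c("u_kin", "eta"),
          method = config$coupling_method, fit_window = window_K))
    } else {
      note("coupling_eta", "skipped", "no viscosity data")
    }
    if (!is.null(kinetics$tau_alpha_s)) {
      coupling$u_kin_vs_tau_alpha <- run_stage("coupling_tau_alpha", TRUE,
        decoupling_exponent(
          list(temperature_K = kelvin_from_celsius(kinetics$temperature_C),
               value = kinetics$tau_alpha_s),
          u_kin_tab, pair_label = c("u_kin", "tau_alpha"),
          method = config$coupling_method, fit_window = window_K))
      coupling$u_kin_vs_D_bulk <- run_stage("coupling_D_bulk", TRUE,
        decoupling_exponent(
          list(temperature_K = kelvin_from_celsius(kinetics$temperature_C),
               value = kinetics$D_bulk_m2_per_s),
          u_kin_tab, pair_label = c("u_kin", "D_bulk"),
          method = config$coupling_method, fit_window = window_K))
    } else {
      note("coupling_tau_alpha", "skipped", "no relaxation-time grid")
      note("coupling_D_bulk", "skipped", "no relaxation-time grid")
    }
  } else {
    note("coupling_eta", "skipped", "no kinetic growth series")
    note("coupling_tau_alpha", "skipped", "no kinetic growth series")
    note("coupling_D_bulk", "skipped", "no kinetic growth series")
  }

  ediger <- run_stage("ediger",
                      !is.null(coupling$u_kin_vs_tau_alpha) && !is.null(frag),
                      compare_to_ediger(coupling$u_kin_vs_tau_alpha, frag))
  report$ediger <- if (!is.null(ediger)) {
    list(m = ediger$m, xi_observed = ediger$xi_observed,
         xi_predicted = ediger$xi_predicted, residual = ediger$residual)
  }

  # -- beta relaxation ---------------------------------------------------
  beta_params <- NULL
  beta_source <- NULL
  if (!is.null(config$tau_beta_csv)) {
    bfit <- run_stage("fit_beta_arrhenius", TRUE,
                      fit_arrhenius(read_relaxation_csv(config$tau_beta_csv, "beta")))
    if (!is.null(bfit)) {
      beta_params <- bfit$parameters
      beta_source <- "fitted"
    }
  } else if (!is.null(config$beta_arrhenius)) {
    beta_params <- config$beta_arrhenius
    beta_source <- "config"
    note("fit_beta_arrhenius", "skipped", "Arrhenius parameters supplied")
  } else {
    note("fit_beta_arrhenius", "skipped", "inputs unavailable")
  }
  report$beta_arrhenius <- if (!is.null(beta_params)) {
    list(tau_inf_s = beta_params$tau_inf, delta_E_J_per_mol = beta_params$delta_E,
         source = beta_source)
  }

  # -- glassy state: layer times, GC coupling, AGV table ----------------
  glassy <- run_stage("glassy_growth",
                      !is.null(config$glassy_growth_csv) &&
                        !is.null(config$geometry),
                      read_growth_csv(config$glassy_growth_csv, "bulk"))
  tau_u_tab <- NULL
  if (!is.null(glassy)) {
    tau_u_tab <- list(temperature_K = glassy$temperature_K,
                      value = layer_time(glassy$u_m_per_s, config$geometry$d_A))
  }
  if (!is.null(tau_u_tab) && !is.null(beta_params)) {
    coupling$tau_u_vs_tau_beta <- run_stage("coupling_tau_beta", TRUE,
      decoupling_exponent(
        list(temperature_K = tau_u_tab$temperature_K,
             value = arrhenius_tau(tau_u_tab$temperature_K, beta_params)),
        tau_u_tab, pair_label = c("tau_u", "tau_beta"),
        method = config$coupling_method))
  } else {
    note("coupling_tau_beta", "skipped", "no glassy growth or beta parameters")
  }

  report$coupling <- lapply(coupling, function(cf) {
    if (is.null(cf)) return(NULL)
    list(pair = paste(cf$pair_label, collapse = "_vs_"), xi = cf$xi,
         slope = cf$slope, intercept = cf$intercept, stderr_xi = cf$stderr_xi,
         r_squared = cf$r_squared, n_points = cf$n_points, method = cf$method,
         interpretation = coupling_coefficient_interpretation(cf))
  })

  report$glassy_table <- run_stage("agv_table",
                                   !is.null(glassy) && !is.null(vft) &&
                                     !is.null(Tg_K), {
    Tk <- glassy$temperature_K
    tau_u <- layer_time(glassy$u_m_per_s, config$geometry$d_A)
    fresh <- agv_tau(Tk, agv_state(vft, T_f = Tg_K))
    equil <- vft_tau(Tk, vft)
    data.frame(temperature_C = celsius_from_kelvin(Tk), tau_u_s = tau_u,
               tau_alpha_fresh_s = fresh, tau_alpha_equilibrated_s = equil,
               layers_fresh = layers_per_alpha_time(fresh, tau_u),
               layers_equilibrated = layers_per_alpha_time(equil, tau_u))
  })

  report$stages <- stages
  report$provenance <- list(config_hash = config_hash(config),
                            seed = config$seed,
                            package_version = as.character(
                              utils::packageVersion("glassgrowth")))
  structure(report, class = "study_report")
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_study_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$fragility)) {
    cat(sprintf("  Tg = %.2f K (%.2f C), m = %.2f (%s)\n", x$Tg_K, x$Tg_C,
                x$fragility$m, x$fragility$classification))
  }
  for (cf in x$coupling) {
    if (!is.null(cf)) {
      cat(sprintf("  %s: xi = %.4g (R^2 = %.4f) -> %s\n",
                  cf$pair, cf$xi, cf$r_squared, cf$interpretation))
    }
  }
  if (!is.null(x$ediger)) {
    cat(sprintf("  fragility-predicted xi = %.3f, residual %+.3f\n",
                x$ediger$xi_predicted, x$ediger$residual))
  }
  failed <- names(Filter(function(s) s$status == "failed", x$stages))
  skipped <- names(Filter(function(s) s$status == "skipped", x$stages))
  if (length(failed)) cat("  failed stages:", paste(failed, collapse = ", "), "\n")
  if (length(skipped)) cat("  skipped stages:", paste(skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.json` carries the full machine-readable report;
#' `report.md` is a short human-readable summary. Re-running on the same
#' inputs overwrites both with identical content (no timestamps are
#' embedded).
#'
#' @param report a [run_pipeline()] result
#' @param outdir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_study_report <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(outdir), sprintf("cannot create directory %s", outdir))
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  md_path <- file.path(outdir, "report.md")
  lines <- c("# Crystal growth / liquid dynamics study report", "")
  if (!is.null(report$fragility)) {
    lines <- c(lines,
               sprintf("- Tg = %.2f C (tau convention), fragility m = %.2f (%s)",
                       report$Tg_C, report$fragility$m,
                       report$fragility$classification))
  }
  for (cf in report$coupling) {
    if (!is.null(cf)) {
      lines <- c(lines, sprintf("- %s: xi = %.4g (R^2 = %.4f, n = %d) -> %s",
                                cf$pair, cf$xi, cf$r_squared, cf$n_points,
                                cf$interpretation))
    }
  }
  if (!is.null(report$ediger)) {
    lines <- c(lines, sprintf(
      "- fragility-based prediction: xi = %.3f (observed %.3f, residual %+.3f)",
      report$ediger$xi_predicted, report$ediger$xi_observed,
      report$ediger$residual))
  }
  lines <- c(lines, "", "## Stages", "")
  for (nm in names(report$stages)) {
    s <- report$stages[[nm]]
    lines <- c(lines, sprintf("- %s: %s%s", nm, s$status,
                              if (nzchar(s$message)) paste0(" (", s$message, ")") else ""))
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}

#' Write a complete synthetic study to disk
#'
#' Generates every dataset of a synthetic study and writes them in the
#' same CSV dialects the pipeline reads, together with a ground-truth
#' JSON (for later recovery scoring) and a ready-to-run pipeline
#' configuration JSON.
#'
#' @param config a [synthetic_study_config()]
#' @param outdir output directory (created if missing)
#' @return invisibly, a named list of the paths written
#' @export
simulate_study <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_study_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(outdir), sprintf("cannot create directory %s", outdir))
  paths <- list(
    spectra = file.path(outdir, "spectra.csv"),
    viscosity = file.path(outdir, "viscosity.csv"),
    growth = file.path(outdir, "growth_bulk.csv"),
    glassy_growth = file.path(outdir, "growth_glassy.csv"),
    tau_beta = file.path(outdir, "tau_beta.csv"),
    truth = file.path(outdir, "truth.json"),
    config = file.path(outdir, "study_config.json"))

  write_spectra_csv(generate_dielectric_spectra(config), paths$spectra)
  write_viscosity_csv(generate_viscosity_dataset(config), paths$viscosity)
  write_growth_csv(generate_growth_dataset(config), paths$growth)
  write_growth_csv(generate_glassy_growth_dataset(config), paths$glassy_growth)
  write_relaxation_csv(generate_beta_relaxation(config), paths$tau_beta)

  truth <- synthetic_truth(config)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  sc <- study_config(
    spectra_csv = paths$spectra, viscosity_csv = paths$viscosity,
    growth_csv = paths$growth, glassy_growth_csv = paths$glassy_growth,
    tau_beta_csv = paths$tau_beta, melting = config$melting,
    geometry = config$geometry, seed = config$seed)
  write_study_config(sc, paths$config)
  invisible(paths)
}

# every generating parameter, flattened for the truth JSON
synthetic_truth <- function(config) {
  v <- config$vft_truth
  Tg <- glass_transition_temperature(v, 100)
  list(
    vft = list(tau0_s = v$tau0, D = v$D, T0_K = v$T0),
    Tg_K = Tg, m = fragility(v, Tg)$m,
    decoupling_xi = config$decoupling_xi_truth,
    growth_prefactor = config$growth_prefactor,
    melting = list(Tm_K = config$melting$Tm,
                   delta_Sm_J_per_molK = config$melting$delta_Sm),
    hn_shape = config$hn_shape_truth,
    beta_arrhenius = list(tau_inf_s = config$beta_arrhenius_truth$tau_inf,
                          delta_E_J_per_mol = config$beta_arrhenius_truth$delta_E),
    viscosity = config$viscosity_truth,
    gc_coupling = config$gc_coupling_truth,
    geometry = list(V_A3 = config$geometry$V_A3, d_A = config$geometry$d_A),
    noise_sigma_log = config$noise_sigma_log,
    temperatures_K = config$temperatures,
    glassy_temperatures_K = config$glassy_temperatures,
    seed = config$seed)
}

#' Score a pipeline report against synthetic ground truth
#'
#' Compares every recovered quantity with its generating value: absolute
#' errors for the decoupling exponents, relative errors for the
#' fragility index, Tg and the VFT parameters.
#'
#' @param report a [run_pipeline()] result
#' @param truth path to a `truth.json` written by [simulate_study()], or
#'   the equivalent list
#' @return a data.frame with columns `quantity`, `fitted`, `truth`,
#'   `error`, `error_type`
#' @export
score_recovery <- function(report, truth) {
  stopifnot(inherits(report, "study_report"))
  if (is.character(truth)) truth <- jsonlite::read_json(truth, simplifyVector = TRUE)
  rows <- list()
  add <- function(quantity, fitted, tru, type) {
    if (is.null(fitted) || is.null(tru)) return()
    err <- if (type == "absolute") fitted - tru else (fitted - tru) / tru
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, fitted = fitted, truth = tru, error = err,
      error_type = type)
  }
  for (nm in c("u_kin_vs_tau_alpha", "u_kin_vs_D_bulk", "u_kin_vs_eta")) {
    add(paste0("xi_", nm), report$coupling[[nm]]$xi, truth$decoupling_xi,
        "absolute")
  }
  add("xi_tau_u_vs_tau_beta", report$coupling$tau_u_vs_tau_beta$xi,
      truth$gc_coupling$xi, "absolute")
  add("m", report$fragility$m, truth$m, "relative")
  add("Tg_K", report$Tg_K, truth$Tg_K, "relative")
  add("D", report$vft$D, truth$vft$D, "relative")
  add("T0_K", report$vft$T0_K, truth$vft$T0_K, "relative")
  do.call(rbind, rows)
}
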