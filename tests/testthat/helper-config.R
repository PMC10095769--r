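# shared synthetic configs: nimesulide-like defaults, noise off unless asked
noiseless_config <- function(seed = 1L, ...) {
  synthetic_study_config(noise_sigma_log = 0, seed = seed, ...)
}

# defaults with the viscosity sharing the alpha-relaxation VFT triple, so
# every exact power law in tau_alpha is the same power law in eta
coupled_config <- function(seed = 1L, noise_sigma_log = 0, ...) {
  synthetic_study_config(
    noise_sigma_log = noise_sigma_log,
    viscosity_truth = viscosity_truth_coupled(vft_from_tg_fragility(296.15, 85)),
    seed = seed, ...)
}

# closed-form OLS slope/intercept, the independent oracle for regressions
ols_closed_form <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}
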