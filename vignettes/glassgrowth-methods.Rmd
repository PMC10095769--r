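---
title: "Linking crystal growth kinetics to liquid dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking crystal growth kinetics to liquid dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassgrowth)
```

## The scientific problem

Amorphous (glassy) formulations of poorly soluble drugs dissolve faster
than their crystalline forms, but they are thermodynamically unstable:
sooner or later they crystallize, and sometimes — notably in the
glass-to-crystal (GC) growth mode near and below the glass transition —
orders of magnitude faster than any diffusion-controlled model predicts.
Deciding which measure of molecular mobility actually controls crystal
growth is therefore central to predicting the shelf life of an amorphous
solid. This package implements the full analysis chain for one drug-like
glass former: characterize the liquid dynamics (dielectric relaxation,
viscosity), extract the mobility-limited part of measured crystal growth
rates, quantify how strongly the two decouple, and extrapolate structural
relaxation into the glassy state to ask whether growth there outruns it.

## Models

### Dielectric relaxation

A broadband dielectric spectrum at one temperature is fitted with a
single Havriliak–Negami (HN) process plus a dc-conductivity term:

$$\varepsilon^*(\omega) = \varepsilon_\infty +
\frac{\varepsilon_s - \varepsilon_\infty}
     {\bigl(1 + (i\omega\tau_{HN})^{\alpha}\bigr)^{\beta}}
 + \frac{\sigma_{dc}}{i\omega\varepsilon_0},$$

with width and asymmetry shape parameters $\alpha, \beta \in (0,1]$
($\alpha=\beta=1$ is Debye, $\beta=1$ Cole–Cole). The model-free
structural relaxation time is the inverse angular frequency of the loss
peak,

$$\tau_\alpha = \tau_{max} = \tau_{HN}\,
\Bigl[\sin\tfrac{\pi\alpha}{2+2\beta}\Bigr]^{-1/\alpha}
\Bigl[\sin\tfrac{\pi\alpha\beta}{2+2\beta}\Bigr]^{1/\alpha},$$

which reduces to $\tau_{HN}$ exactly in the Debye and Cole–Cole cases.
`fit_hn()` fits $\varepsilon'$ and $\varepsilon''$ jointly with
*relative* residual weighting: the loss spans several decades across the
0.1 Hz–1 MHz window and absolute residuals would be dominated by the
conductivity tail. Nothing in the raw data says which part carries more
information, so both enter symmetrically.

### Temperature dependence of mobility

Above $T_g$ the relaxation time follows the Vogel–Fulcher–Tammann (VFT)
law $\tau(T) = \tau_0 \exp[D T_0/(T - T_0)]$. `fit_vft()` fits on
$\log_{10}\tau$ (even weighting across decades) and by default pins
$\tau_0 = 10^{-14}\,$s, the quasi-lattice vibration period; free-$\tau_0$
fitting is available behind a flag, but with the usual 4–6 decades of
data $\tau_0$ and $D$ are strongly correlated and pinning is the
standard practice. The operational glass transition is the temperature
where $\tau$ reaches a conventional value (100 s by default,
user-overridable when a calorimetric $T_g$ is preferred), available in
closed form. The dynamic fragility is the steepness index

$$m = \left.\frac{d\log_{10}\tau}{d(T_g/T)}\right|_{T=T_g}
    = \frac{D\,(T_0/T_g)}{(1 - T_0/T_g)^2 \ln 10},$$

which under the $10^{-14}$ s / 100 s conventions has the Arrhenius
(strong) limit $m = 16$. Classification thresholds: $m<30$ strong,
$30 \le m < 100$ intermediate, $m \ge 100$ fragile — consistent with
calling $m \approx 85$ an intermediate glass former.

Below $T_g$ the equilibrium VFT law no longer applies; the
Adam–Gibbs–Vogel (AGV) form

$$\tau(T) = \tau_0 \exp\!\left[\frac{D T_0}{T\,(1 - T_0/T_f)}\right]$$

interpolates via the fictive temperature $T_f$: $T_f = T_g$ for a fresh
glass (frozen configuration; the branch is then exactly Arrhenius in
$1/T$) and $T_f = T$ for a fully equilibrated glass, where AGV reduces
to VFT. The package implements only these two printed limits; aging
kinetics of $T_f$ between them (Tool–Narayanaswamy) is out of scope.
The secondary (Johari–Goldstein-type) $\beta$ relaxation is modelled as
Arrhenius, $\tau_\beta = \tau_\infty \exp[\Delta E_\beta/(RT)]$, with a
molar activation energy — barriers are reported in kJ/mol, so the molar
gas constant is the dimensionally consistent choice.

### Growth kinetics and decoupling

A measured growth rate mixes mobility and thermodynamics. The kinetic
part is isolated by dividing out the driving-force factor,

$$u_{kin} = \frac{u}{1 - \exp[-\Delta S_m (T_m - T)/(RT)]},$$

with $\Delta S_m$ the melt–crystal entropy difference at $T_m$ (supplied
directly or as $\Delta H_m/T_m$; the constant-$\Delta S_m$ form is used
at all temperatures). The factor tends to 1 at deep undercooling and to
0 at $T_m$, where the division amplifies noise — a warning fires when it
drops below 0.05. Bulk diffusivity is predicted from the relaxation time
and the molecular diameter, $D_{bulk} = d^2/(6\tau_\alpha)$, with
$d = 1.12\,V^{1/3}$ from close packing of spheres occupying 74% of the
per-molecule volume $V$.

Decoupling is quantified by ordinary least squares on the log–log scale,
e.g. $\log_{10} u_{kin} = -\xi \log_{10}\tau_\alpha + A$; $\xi$ is
reported as the magnitude of the slope with the sign convention recorded
per pair ($u_{kin}$ falls with $\eta$ and $\tau_\alpha$, rises with
$D_{bulk}$; the glassy-state layer time $\tau_u = d/u$ rises with
$\tau_\beta$). $\xi \approx 1$ means the mobility measure controls the
kinetics; $\xi$ well below 1 means enhancement over the Stokes–Einstein
expectation; $\xi > 1.1$ means the kinetics have a larger activation
energy than the relaxation, which therefore cannot be triggering them
("not controlling"). The observed exponent is compared against the
empirical fragility correlation $\xi \approx 1.1 - 0.005\,m$.

Temperature matching between series is an exact-key join (micro-kelvin
rounding); no interpolation is performed, because interpolating
$\log\tau$ near $T_g$ — where it changes by a decade per few kelvin —
would silently dominate the regression. An optional temperature window
restricts the fit to the intermediate/deep supercooled region, and a
Deming variant (error-variance ratio 1) is available since both
variables are measured; OLS is the default because no weighting
information usually exists.

## The synthetic-data generator

`synthetic_study_config()` defines a complete ground-truth study of a
nimesulide-like material, and `simulate_study()` writes it in the same
CSV dialects the pipeline reads. The defaults are the package's fixed
emulation of that material, chosen once:

* **VFT truth.** No literature VFT triple is available, so the defaults
  are solved in closed form from the conventions $\tau_0 = 10^{-14}$ s,
  $\tau(T_g) = 100$ s at $T_g = 296.15$ K (23 °C) and $m = 85$, giving
  $T_0 = T_g(1 - 16/m) \approx 240.40$ K and $D \approx 8.54$. These are
  synthetic values consistent with the printed $T_g$ and fragility, not
  measured parameters.
* **Growth.** $u = C\,\tau_\alpha^{-\xi}\,[1 - e^{-\Delta S_m \Delta T/RT}]$
  with $\xi = 0.65$, $C = 10^{-11}$ m/s·s$^{\xi}$, $T_m = 420.15$ K and
  $\Delta S_m = 80$ J/(mol K) ($\approx \Delta H_m/T_m$ for a typical
  drug-sized organic molecule). This puts growth rates near 0.1 µm/s at
  the mobility/driving-force crossover — the scale seen under a hot-stage
  microscope.
* **Dielectric.** One HN process ($\alpha = 0.8$, $\beta = 0.6$,
  $\Delta\varepsilon = 2$) with $\tau_{HN}$ set per temperature by
  inverting the loss-peak formula so that $\tau_{max}$ equals the VFT
  truth, plus $\sigma_{dc} = 10^{-11}$ S/m, on the 0.1 Hz–1 MHz
  instrument window at 10 points per decade. The default 35–80 °C grid
  keeps every loss peak inside the window.
* **Viscosity.** Its own VFT triple, zero-mobility temperature 2.4 K
  below that of $\tau_\alpha$ and scaled to $10^{12}$ Pa s at $T_g$ —
  a slight, systematic decoupling of the kind produced by relating
  oscillatory to steady shear flow. Over 35–80 °C it spans about five
  orders of magnitude. `viscosity_truth_coupled()` instead shares the
  $\tau_\alpha$ triple; the noiseless end-to-end recovery checks use it,
  because a constant $u_{kin}$–$\eta$ exponent only exists exactly when
  $\log\eta$ is affine in $\log\tau_\alpha$.
* **Glassy state.** $\beta$-relaxation Arrhenius truth
  $\tau_\infty = 6.31\times10^{-15}$ s, $\Delta E_\beta = 41.9$ kJ/mol;
  glass-to-crystal growth generated through
  $\log_{10}\tau_u = 2.20\,\log_{10}\tau_\beta + 14$, which yields
  GC-like rates of a few tenths of nm/s at 0–18 °C and layer counts far
  above 30 per structural relaxation.
* **Geometry.** $V = 244$ Å$^3$ per molecule, i.e. $d = 7.0$ Å.
* **Noise.** Multiplicative lognormal — Gaussian of width
  `noise_sigma_log` (default 0.02) on $\log_{10}$ of every positive
  observable, since all of them span decades. Every generator is a pure
  function of (config, seed), with per-dataset seed offsets so that
  generating one dataset never perturbs another.

What the generator does *not* emulate: electrode polarization and
multi-process dielectric spectra, temperature-dependent $\Delta S_m$,
the bell-shaped maximum of $u(T)$ near $T_m$ (the default grid sits on
its low-temperature flank), surface-growth jumps, spherulite morphology,
or aging. Passing the recovery tests therefore demonstrates that the
estimators invert the stated forward models at realistic noise, not that
real spectra are this clean.

## Numerical choices

* **HN fitting.** Levenberg–Marquardt (`minpack.lm`) with box bounds:
  $\alpha, \beta \in (0.05, 1]$, strength parameterized as
  $\Delta\varepsilon = \varepsilon_s - \varepsilon_\infty > 0$,
  $\sigma_{dc} \ge 0$, $\tau_{HN}$ fitted as $\log_{10}\tau$. Seven
  multi-start values of $\log_{10}\tau_{HN}$ span the inverse frequency
  window; the restart with the smallest residual norm wins, ties broken
  by the smallest $\tau_{HN}$. A fit whose implied loss peak lands more
  than a decade outside the measured window is flagged as not converged
  (a spectrum with no resolvable relaxation, e.g. pure conductivity).
* **VFT fitting.** Same machinery on $\log_{10}\tau$ with three $T_0$
  starts (0.6, 0.75, 0.9 × the lowest data temperature) and the bound
  $T_0 < \min T$; at least four points required.
* **Degenerate inputs.** Spectra need ≥ 8 points spanning ≥ 2 decades;
  coupling fits need ≥ 3 shared temperatures and strictly positive
  values; $T \ge T_m$ (no undercooling), $T \le T_0$ (VFT divergence)
  and $T_f \le T_0$ are errors, not NaNs.
* **Exactness.** The AGV law with $T_f = T$ equals VFT analytically but
  not bitwise (different floating-point groupings of the exponent);
  identities of this kind are asserted at $10^{-12}$ relative.

## The pipeline

`run_pipeline()` sequences ingest → HN fits → VFT → $T_g$ → fragility →
driving-force correction → $D_{bulk}$ → coupling fits ($\eta$,
$\tau_\alpha$, $D_{bulk}$) → fragility-line comparison → $\beta$
Arrhenius (fitted from data or taken from config) → glassy
$\tau_u$–$\tau_\beta$ coupling → the AGV fresh/equilibrated table.
Relaxation times on the growth-temperature grid come from the *fitted*
VFT law, extended over the growth range, mirroring how sparse dielectric
grids are reconciled with microscopy grids in practice. Missing inputs
skip the dependent stages (recorded per stage); failures are recorded
with the stage name and never abort the run. Reports carry no
timestamps, so re-running the same config yields byte-identical output;
provenance is a config hash, the seed and the package version.

## Problem sizes and runtime

The validation suite uses the study conditions stated above: 10
temperatures (35–80 °C) for spectra/viscosity/growth, 5 glassy
temperatures (0–18 °C), 71-point frequency grids, noise
$\sigma_{\log_{10}} = 0.05$ for relaxation/growth recovery and
$\log_{10}(1.02)$ (≈2% multiplicative) for spectra; exponent-recovery
statistics use 15 temperatures × 200 seeds per ground-truth value. The
full suite runs in well under a minute; the end-to-end pipeline takes a
few seconds.

## Known limitations

* One HN process only: no $\beta$-process deconvolution from spectra,
  no electrode-polarization correction, no derivative-based
  conductivity-free loss.
* The constant-$\Delta S_m$ driving force is used at all undercoolings.
* Surface growth series are carried separately but no surface-diffusion
  model is provided; the decoupling analysis applies to bulk growth.
* The fragility correlation comparison assumes the exponent was obtained
  from supercooled-liquid growth kinetics; layer-time/$\beta$ pairs are
  rejected by construction.
* With the default mildly decoupled viscosity, the $u_{kin}$–$\eta$
  exponent is an effective value over the fitted window, not a constant
  of the model; only the coupled-viscosity option makes it exact.
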