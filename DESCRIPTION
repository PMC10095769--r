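Package: glassgrowth
Title: Crystal Growth Kinetics and Liquid Dynamics of Amorphous Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links crystal growth kinetics of amorphous (glass-forming)
    pharmaceuticals to their liquid dynamics. Fits the Havriliak-Negami
    model with a dc-conductivity term to broadband dielectric spectra and
    converts the fitted parameters to alpha-relaxation times; fits the
    Vogel-Fulcher-Tammann equation and derives an operational glass
    transition temperature and the dynamic fragility index; extracts the
    kinetic part of measured crystal growth rates by dividing out the
    thermodynamic driving-force factor; predicts bulk molecular
    diffusivities from relaxation times and molecular diameters; quantifies
    Stokes-Einstein-type decoupling between growth kinetics and each
    mobility measure by log-log regression and compares the exponent with
    the fragility-based linear prediction; and extrapolates structural
    relaxation into the glassy state with the Adam-Gibbs-Vogel equation for
    fresh and fully equilibrated glasses. A seeded synthetic-data generator
    emulating a nimesulide-like drug provides ground-truth studies for
    validation, and a config-driven pipeline runs the whole analysis from
    CSV inputs to a JSON/Markdown report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
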