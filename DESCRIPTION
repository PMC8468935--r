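Package: nirmeat
Title: Vis/NIR Chemometrics for Meat Quality Prediction
Version: 0.1.0
Authors@R: person("nirmeat", "developers", role = c("aut", "cre"),
    email = "nirmeat@example.org")
Description: Tools for building and evaluating visible/near-infrared (Vis/NIR)
    reflectance calibrations of meat physicochemical properties (pH, CIELAB
    colour, cooking loss, shear force). Implements the standard chemometric
    preprocessing operators (Savitzky-Golay smoothing and derivatives,
    multiplicative scatter correction, standard normal variate, polynomial
    detrending), two calibration/prediction sample-set division schemes
    (concentration-gradient and whole-carcass hold-out), partial least squares
    regression (univariate NIPALS) with leave-one-out cross-validated latent
    variable selection, and RPD-graded model reports. Ships a seeded synthetic
    spectra generator emulating a multi-cut sheep-meat study design so the
    whole pipeline is testable without instrument data, plus a small command
    line interface for reproducible end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
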