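Package: ignorance
Title: Ignorance Scores and Geographic Drivers of Sampling Bias in
    Citizen-Science Observation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies spatial sampling bias in presence-only species
    observation data using per-grid-cell 'ignorance' scores computed with the
    half-ignorance algorithm, and models those scores against geographic
    accessibility covariates. Provides gridding of observation records,
    ignorance-score sweeps over the half-ignorance threshold, construction of
    covariate layers (slope from elevation, road and path line density,
    population density from census polygons), Bayesian Beta regression with a
    logit link fitted by adaptive random-walk Metropolis, nested model
    selection by deviance differences against chi-squared quantiles, deviance
    R-squared, fitted ignorance curves and extraction of covariate threshold
    values where ignorance crosses a target score. Includes a synthetic
    landscape and observation generator so the full pipeline can be exercised
    and calibrated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
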