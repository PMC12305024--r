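Package: photoniche
Title: Visual Ecology and Phylogenetic Comparative Analysis of Forest
    Light Microhabitats
Version: 0.1.0
Authors@R:
    person("photoniche", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking rainforest light microhabitats to trait
    evolution in butterfly communities. Converts spectral irradiance
    measurements into receptor quantum catches and Michelson relative
    catches under a trichromatic (UV/B/LW) visual model, estimates canopy
    openness from hemispherical fisheye photographs, measures flight-related
    wing morphology from silhouettes, builds ecological axes by principal
    component analysis of species means, and provides phylogenetic
    regression (PGLS with Pagel's lambda, Gaussian phylogenetic mixed
    models, standardized major axis tests) together with single- and
    multipeak Brownian motion, Ornstein-Uhlenbeck and early-burst models of
    trait evolution fitted over ensembles of stochastic character maps.
    Includes a fully deterministic synthetic-community generator so every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
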