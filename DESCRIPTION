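Package: phytomet
Title: Metabolic Scaling Analysis of Phytoplankton Community Metabolism
Version: 0.1.0
Authors@R: person("Analysis", "Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to link phytoplankton community metabolism (gross primary
    production and community respiration measured as oxygen flux) to the
    individual size distribution and environmental temperature using metabolic
    scaling theory. Provides the forward Boltzmann-Arrhenius / size-scaling
    model, a simulator for warmed and ambient mesocosm communities, Eilers-type
    photosynthesis-irradiance curve fitting with multistart nonlinear least
    squares, maximum-likelihood estimation of the activation energy and
    size-scaling exponent with profile confidence intervals and likelihood
    ratio model comparison, standardised major axis regression machinery for
    the proportionality (slope 1) and metabolic compensation (slope -1) tests,
    cytometry size-to-carbon conversion, and first-principles community
    composition statistics (rarefaction, Bray-Curtis, PCoA, PERMANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
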