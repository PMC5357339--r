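Package: ragrisk
Title: Presence-Only Habitat Suitability and Allergy-Risk Area Change Under Climate Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for presence-only species distribution
    modelling of wind-pollinated allergenic plants on an equal-area grid:
    occurrence-record cleaning (coordinate, elevation and per-cell duplicate
    filters), derivation of three bioclimatic predictors (growing degree days,
    absolute minimum temperature of the coldest month, and annual water
    balance via Thornthwaite potential evapotranspiration), an l1-penalized
    maximum-entropy suitability model with linear/quadratic/product/hinge
    features and AICc tuning, replicate fitting with presence/background AUC,
    jackknife variable importance and MESS extrapolation surfaces, and
    quartile-threshold 'high allergy risk' area-change statistics under
    future climate scenarios. Includes a synthetic-data generator with known
    ground truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
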