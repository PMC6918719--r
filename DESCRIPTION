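Package: routescape
Title: Habitual Route Networks, Resource Visibility and Landscape Models
    for Arboreal Movement Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs habitual route networks from GPS travel bouts of
    group-living arboreal animals, estimates kernel home ranges, quantifies
    food-tree interception along routes against a complete-spatial-randomness
    Monte Carlo null, computes per-quadrat landscape covariates (slope,
    elevation, canopy-gap coverage, a food-tree visibility index), and fits
    spatial-autocorrelation-adjusted linear and generalized linear mixed
    models for route placement. Includes a synthetic-data generator that
    plants known route networks, tree distributions and effect sizes so every
    stage of the pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
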