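Package: occuhier
Title: Two-Scale Bayesian Occupancy Models with Conflict Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical site-occupancy models in which a species
    occupies large grid cells and uses finer subgrid cells within them,
    with imperfect detection on repeated 100-m sign-survey segments.
    Occupancy, use and detection probabilities vary logistically with
    environmental covariates, and a prey-use layer feeds the
    predator-use layer. Inference is by Metropolis-within-Gibbs data
    augmentation with split-chain Gelman-Rubin diagnostics. Includes
    covariate preparation (standardization, population-density flooring
    and log transform, neighbour-mean prey imputation), a synthetic
    survey generator for simulation-based validation, posterior use
    maps, stratified 2x2 odds-ratio association and homogeneity tests
    for wildlife-conflict records, and harmonic regression for monthly
    seasonality of conflict events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
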