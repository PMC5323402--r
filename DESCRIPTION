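Package: cropdyn
Title: Population-Dynamics Analysis of Crop Yield Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing annual crop-yield time series with
    Royama-type R-function (Ricker) models. Detrends log-yield series,
    constructs rates of increase, diagnoses feedback order with the
    partial rate correlation function (PRCF), fits pure and externally
    perturbed (lateral, vertical, nonlinear) rate models by nonlinear
    least squares, ranks candidates by AICc with Akaike weights and
    confidence sets, and reports equilibria (yield potential) and
    stability slopes. Includes weed-community diversity utilities
    (Shannon, Simpson, inverse Simpson, J- and E-evenness, Hellinger
    transformation, rare-species filtering, index-species correlation
    screening) and a synthetic-data generator that emulates a
    block-replicated long-term agricultural experiment for testing the
    full pipeline with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
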