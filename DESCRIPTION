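Package: plateauSDM
Title: Bayesian Plateau Species Distribution Models with Physiological Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits Bayesian plateau (trapezoidal envelope) species distribution
    models to presence/pseudo-absence data, with either vague ("naive") priors
    or physiologically informed priors that pin the response plateau and its
    descending slope to laboratory-derived tolerance limits (e.g. an optimal
    temperature range and an upper thermal limit). Includes a seeded synthetic
    coastal-landscape generator with known ground truth, occurrence cleaning
    and spatial thinning, buffered calibration areas, pseudo-absence sampling,
    spatial block cross-validation with the continuous Boyce index, permutation
    variable importance, marginal response curves, and projection analytics
    (omission-threshold binarization, Jaccard range stability across
    calibration extents, range expansion/contraction under warming, and paired
    Wilcoxon contrasts).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
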