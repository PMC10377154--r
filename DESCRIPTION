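Package: tempshift
Title: Gaussian Process Detection of Temporal Shifts between Expression
    Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies time-series gene-expression trajectories measured in
    two or more groups (conditions, tissues, brain areas) into genes with
    different trajectory shapes (DiffShape), genes whose shared trajectory is
    temporally shifted between groups (shift), and genes with identical
    trajectories (no-shift). Each gene is fitted with three zero-mean
    Gaussian-process regression models built on the squared-exponential
    kernel -- an independence model, a shift model with per-group time
    offsets, and a no-shift model -- and classified by log-likelihood
    ratios of their maximized marginal likelihoods. The temporal offset of
    each group relative to a reference is estimated in the shift model.
    Includes simulators for Gaussian-process, periodic and polynomial
    benchmark data with known ground-truth shifts, a cubic-regression
    pre-selection filter for temporally dynamic genes, and a reproducible
    table-in/table-out pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    MASS,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
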