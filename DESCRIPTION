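Package: eatr
Title: Time-Dependent Rate Estimation and Reaction-Coordinate Quality for
    Biased Molecular Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers unbiased kinetic rates from metadynamics-style biased
    molecular simulations and scores reaction-coordinate (RC) quality with
    the dimensionless gamma metric. Implements the infrequent-metadynamics
    acceleration factor and accelerated time, survival-function maximum
    likelihood estimation of (k0, gamma) under the iMetaD, Kramers
    time-dependent rate (KTR) and exponential-average time-dependent rate
    (EATR) hazard models with right-censoring and bootstrap uncertainties,
    closed-form moment-based gamma predictors, a Poisson-CDF fit with a
    Kolmogorov-Smirnov diagnostic, PLUMED COLVAR/HILLS text I/O, and
    synthetic generators (inhomogeneous-Poisson time rescaling and a 2D
    Langevin double-well with history-dependent Gaussian bias along a
    rotatable collective variable) that make every estimator testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
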