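Package: mixsvr
Title: Mixed-Kernel Support Vector Regression for Disease-Progression Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Epsilon-insensitive support vector regression with composable
    Mercer kernels (radial basis, polynomial, convex-sum and product
    mixtures), solved by a sequential minimal optimization (SMO) dual solver
    with Karush-Kuhn-Tucker diagnostics.  Includes empirical positive
    semi-definiteness checks for kernel admissibility, grid-search
    hyperparameter tuning, subject-preserving data splits for
    repeated-measures voice-telemonitoring data, gender-by-age patient
    grouping, regression metrics with gain summaries, and a synthetic
    generator that emulates Parkinson's telemonitoring cohorts (repeated
    voice recordings with collinear jitter/shimmer feature blocks and
    linearly interpolated UPDRS anchor visits).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
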