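Package: vmetric
Title: Rank-Valuation (v Metric) Transform and Clustering Harness for Omics Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a p-adic-inspired rank-valuation transform (the "v
    metric") for strictly positive entity-by-sample omics matrices
    (proteomics intensity scores, microarray signals, 2^induction-factor
    values), together with the clustering and evaluation harness needed to
    assess whether the transform stabilises sample clustering in high
    dimensions: the seven classical Lance-Williams agglomerative methods
    driven by an explicit coefficient table, Lloyd k-means with restarts,
    alternative dissimilarities (Euclidean, squared and half-squared
    Euclidean, correlation distance, radial-basis kernel, Clark-Evans
    nearest-neighbour index), rank-ordered variance diagnostics with a
    rank-wise outlier-exceedance rule, Welch t-tests with confidence
    intervals, PCA reports with per-sample correlations, a synthetic
    Zipf/log-Boltzmann data generator with group effects and heavy-tailed
    spike contamination, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
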