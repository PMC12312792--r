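Package: kernelde
Title: Distribution-Based Differential Expression for Multi-Subject Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential expression testing for multi-subject single-cell
    RNA-seq and mass cytometry data that treats each subject's per-gene
    expression as a probability distribution. Subjects are compared by the
    Jensen-Shannon divergence between kernel density estimates on a shared
    grid, and group differences are tested either by distance-matrix
    regression with a square-root pseudo-F statistic and hierarchical
    adaptive permutation inference, or by a semiparametric kernel score
    test with a weighted chi-square null. Includes a synthetic-data
    generator covering the five differential-distribution archetypes
    (DE, DP, DM, DB, DV), pure-null designs and cell-type-specific batch
    effects, plus MatrixMarket/CSV readers and writers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
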