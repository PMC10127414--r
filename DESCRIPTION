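Package: scnet
Title: Structural Covariance Networks of Subcortical Volumes in
    Subjective Cognitive Decline
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for navigation-based subgrouping of
    subjective cognitive decline cohorts and group-level structural
    covariance networks of subcortical volumes. Provides a synthetic
    cohort generator with group-specific volumetric and covariance
    structure, covariate-adjusted volumetric statistics (ANCOVA with LSD
    post hoc and false discovery rate correction), exact count-based
    tests, partial correlations, sparsity-thresholded binary covariance
    networks over basal forebrain and right hippocampal subfields,
    small-world graph metrics normalized against degree-preserving random
    networks, and permutation inference on area-under-the-curve network
    statistics across a sparsity grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    readr,
    emmeans,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
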