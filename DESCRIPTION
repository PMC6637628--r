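Package: gutplane
Title: Longitudinal Gut Microbiome Dysbiosis Analysis for Experimental
    Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal shotgun-metagenomic studies
    of experimental arthritis in rats. Summarizes community trajectories as
    Euclidean distances to "healthy" and "disease" planes fitted by total
    least squares in Bray-Curtis principal-coordinate space; selects
    arthritis-correlated species by repeated cross-validated non-negative
    elastic-net regression with consensus filtering; calls significant
    per-rat normal-referenced log10 fold changes; computes covariate-adjusted
    semi-partial Spearman correlations between taxa, plane distances and
    serum cytokines; and tests KEGG orthologs and modules for differential
    abundance. Includes a synthetic cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
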