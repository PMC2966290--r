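Package: l1l2dap
Title: Quantitative Phenotype Prediction from SNP Genotypes with L1L2
    Regression, Stability-Aware Model Selection and SNP Saturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts quantitative phenotypes from genome-wide SNP genotypes
    with the L1L2 method: a naive elastic net solved by iterative
    soft-thresholding, followed by a regularized least squares (ridge) refit
    on the selected support to correct the shrinkage bias of the naive
    weights.  Model selection follows a reproducible Data Analysis Protocol
    with family-respecting development/validation resamplings, internal
    cross-validation over a hyperparameter grid, and a selection rule that
    trades prediction accuracy against the stability of the ranked marker
    lists, measured by the Canberra distance for partial ranked lists.  A
    saturation step recovers SNPs in linkage disequilibrium with top-ranked
    markers via genotype-profile correlation.  Includes PLINK-style text
    genotype input, genotype encodings and frequency-based imputation, a
    Gaussian-kernel support vector regression baseline protocol, and a
    family-structured synthetic cohort simulator with LD blocks and sparse
    additive effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
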