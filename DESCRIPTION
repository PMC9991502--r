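Package: megafactor
Title: Bayesian Sparse-Factor Whole-Genome Regression for Many-Trait
    Prediction and Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate whole-genome regression for a focal trait assisted
    by thousands of correlated secondary traits. Observed traits are decomposed
    onto a small number of latent factors whose genetic values are multiple
    regressions on marker dosages with BayesC spike-and-slab priors; factor
    loadings carry a spike-and-slab prior with multiplicative gamma shrinkage
    across factors. Includes a ridge (RR-BLUP) variant, univariate BayesC and
    single-marker scan baselines, a two-stage marker-preselection pipeline with
    LD clumping, GBLUP baselines with one or two kernels, masked
    cross-validation with heritability-corrected accuracy and a
    resampling-adjusted t-statistic, MCMC diagnostics, and simulators for
    factor-structured phenotypes on independent or LD-patterned genotypes.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
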