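Package: cyclegp
Title: Multi-Cycle Genomic Prediction and Validation for Clonal Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction across
    overlapping cycles of an elite clonal breeding program. Simulates
    multi-cycle populations from a partial circular mating design with
    carry-over of common genotypes, adjusts replicated field-trial phenotypes
    to per-genotype BLUEs by REML (with optional spatial row/column effects
    and separable AR1xAR1 residuals), fits Bayes B spike-and-slab and GBLUP
    whole-genome regression models, evaluates forward and backward cross-cycle
    predictive ability with and without common genotypes, estimates
    heritability and factor-analytic genotype-by-year genetic correlations,
    and characterises linkage disequilibrium (plain and relatedness-corrected)
    together with LD-based effective population size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils,
    minpack.lm,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
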