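Package: tablup
Title: Genomic Prediction with Trait-Specific Marker-Derived Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and genomic evaluation toolkit for trait-specific
    genomic best linear unbiased prediction (TABLUP). Includes a
    forward-in-time mutation-drift population simulator (Haldane
    recombination, infinite-alleles mutation, biallelic recoding, a
    half-sib multi-generation validation design), marker-effect estimation
    by ridge-regression BLUP and BayesB Markov chain Monte Carlo,
    construction of unweighted and trait-specific weighted identity-by-state
    relationship matrices, Gauss-Seidel solution of Henderson's mixed model
    equations, and tidy evaluation of prediction accuracy, rank correlation,
    bias and persistency across generations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
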