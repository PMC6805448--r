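Package: beeval
Title: Pedigree-Based Genetic Evaluation of Honey Bee Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic evaluation of honey bee (Apis mellifera) colony
    performance from maternal-only pedigrees. Builds the two-tier
    queen/worker-group pedigree and the inverse numerator relationship
    matrix, fits colony models with either worker-direct plus
    queen-maternal genetic effects or a single queen-direct effect by
    average-information REML (continuous traits) and threshold-model
    Gibbs sampling (5-category behaviour scores, single- and
    multi-trait), converts variance components into heritabilities and
    genetic correlations, and measures model predictability by
    record-removal cross-validation. Includes a synthetic
    breeding-program generator emulating a national queen registry so
    the whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
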