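Package: delaytree
Title: Dating Unobserved Cell-Fate Decisions from Delayed Lineage-Marker
    Onsets in Single-Cell Genealogies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the time point of unobserved cell-fate decisions from
    correlated, delayed lineage-marker onsets in time-lapse genealogies of
    dividing cells. Combines a memory-less differentiation process with a
    linear time-dependent hazard and a stochastic birth-death gene-expression
    delay with an absorbing detection threshold. Tree likelihoods sum over all
    differentiation scenarios ("hidden trees") by dynamic programming with
    sum-product message passing over the expression state; maximum-likelihood
    fitting uses Latin-hypercube multistart optimization. Includes a forward
    simulator of annotated genealogies, a branching-process model of colony
    assay frequencies, a Gillespie simulator of a tristable toggle switch on
    dividing lineages, and per-cell marker-slope statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    lhs,
    ape,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
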