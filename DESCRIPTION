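Package: songphylo
Title: Phylogenetic Comparative Analysis of Song-Learning Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of open- versus closed-ended
    song learning in oscine songbirds. Implements discrete-trait
    continuous-time Markov (Mk) models with maximum-likelihood fitting,
    marginal ancestral states and stochastic character mapping;
    state-dependent (multi-rate) Brownian-motion tests over stochastic-map
    ensembles; simulation-based phylogenetic ANOVA with post-hoc tests and
    Holm-Bonferroni correction; phylogenetic generalized least squares with
    Pagel's lambda; Pagel's correlated-evolution test for binary trait
    pairs driven by an exhaustive threshold sweep of continuous song
    traits; and a synthetic-data generator that emulates the joint
    structure of song-learning, song-characteristic and mating-system
    data on a phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
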