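Package: coopnet
Title: Cooperative Voter Model of Ecological Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic birth-death (voter-type) model of ecological
    communities with mediated cooperation, exploitation and harmful
    interactions. Implements exact Gillespie simulation of the finite
    community Markov process, its deterministic mean-field limit with
    Perron-Frobenius stationary states and extinction (pruning) cascades,
    linear-noise (Ornstein-Uhlenbeck) fluctuation theory with Lyapunov
    stationary covariances, random-matrix stability analysis (eigenvalue
    ellipse predictions), relative species abundance patterns, and
    reproducible in-silico experiments with a command line entry point.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
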