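Package: dcgiv
Title: Directed Cyclic Graph Causal Discovery from Longitudinal Data with
    Instrumental Variables
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous discovery of time-lagged and possibly cyclic
    instantaneous causal relationships among continuous longitudinal
    outcomes.  Implements a linear non-Gaussian structural causal model
    with feedback loops, the ICA equivalence-class machinery (admissible
    row-permutations, cycle-reversal surgery, exhaustive class
    enumeration) together with instrument-based uniqueness certificates,
    spike-and-slab Bayesian structural learning with a
    stability-constrained Metropolis-within-Gibbs sampler, panel
    simulators with Laplace scale-mixture errors, and replicated
    experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
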