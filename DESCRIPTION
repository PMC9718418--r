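Package: crnlearn
Title: Stochastic Chemical Reaction Networks for Probabilistic
    Decision-Making and Operant Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Build and simulate stochastic chemical reaction networks that
    make tunable, population-level probabilistic decisions through a
    stimulus-activated approximate-majority motif, and condition those
    decision probabilities over time with Good/Bad feedback from a simulated
    environment.  Provides an exact Gillespie direct-method simulator with
    runtime perturbations and reproducible seeding, a motif library for
    composing k-way decision systems (entropy generation, approximate
    majority, probability weighting, feedback processing, response
    generation, weight resetting, decision erasure), an environment
    compiler for periodic stimulus schedules with thresholded detection and
    probabilistic feedback policies, and experiment procedures: switching
    transfer curves, weight-to-probability calibration, first-passage reset
    times, sequential decisions, conditioning runs, and ensemble statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
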