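Package: myovstep
Type: Package
Title: Constrained-Diffusion Model of Myosin V Stepping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-analytical model of myosin V stepping on the actin double
    helix. Computes the equilibrium spatial distribution of the detached
    motor head for two stiff semiflexible lever arms under a constrained
    inter-leg joint, a post-power-stroke bound-leg constraint and external
    load; converts it into site-resolved diffusive first-passage binding
    times and the probabilities of the five kinetic pathways (forward and
    backward steps, trailing and leading stomps, termination); and derives
    observables such as step-size distributions, run length, run velocity,
    stall force and the response to off-axis loads. Includes a Metropolis
    oracle and a coarse-grained Brownian-dynamics engine for the bead-chain
    representation, kinetic Monte-Carlo run simulation, and fitting of model
    parameters to step-distribution histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
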