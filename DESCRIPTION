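Package: sossm
Title: Self-Organising State-Space Smoothing for Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint estimation of hidden dynamic states and biophysical
    parameters in stochastic Hodgkin-Huxley-type neuron models from noisy
    current-clamp recordings.  Implements a fixed-lag sequential Monte Carlo
    (particle) smoother over an extended state that carries the model
    parameters, which evolve under an adaptive multivariate-normal proposal
    with covariance-matrix adaptation and a log-normally evolving per-particle
    scale factor, in the spirit of evolution-strategy algorithms.  Ships three
    conductance-based model families (a single-compartment sodium/potassium
    model, a two-compartment motoneuron with calcium dynamics, and a
    single-compartment snail B4-type motoneuron), an Euler-Maruyama simulator
    with random current-step protocols for generating synthetic recordings,
    multi-trace shared-parameter fitting, and scenario runners for parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'smc.R'
    'selforg.R'
    'smoother.R'
    'multitrace.R'
    'experiments.R'
    'cli.R'
    'gates.R'
    'models.R'
    'model-io.R'
    'simulate.R'
    'recording-io.R'
    'utils.R'
    'zzz.R'
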