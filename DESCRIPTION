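Package: NeuralSampling
Title: Spiking-Network Markov Chain Monte Carlo Sampling of Boltzmann
    Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of stochastically spiking neurons whose
    activity implements Markov chain Monte Carlo sampling from Boltzmann
    distributions over binary variables.  Provides the discrete-time
    transition operators with absolute and relative refractory mechanisms,
    the numerical solver for the activation function matched to an arbitrary
    refractory readiness profile, an exact event-driven continuous-time
    jump-process simulator, exhaustive small-system oracles (transition
    matrices, invariance and reversibility diagnostics, Gibbs reference
    sampling), Kullback-Leibler evaluation machinery with Laplace smoothing,
    spike-train firing statistics, and a perceptual-rivalry demonstration
    pipeline with contrastive-divergence training and population-vector
    decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
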