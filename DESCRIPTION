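Package: plasticnet
Title: Recurrent Rate Networks with Diverse Hebbian Learning Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of recurrent rate-based cortical network
    models in which each neuron carries its own Hebbian learning rate.
    Implements Hebbian plasticity with homeostatic synaptic scaling,
    homeostatic inhibitory plasticity, Ornstein-Uhlenbeck input noise, and
    Gabor receptive-field stimulus drive; derived measurements including
    population coupling, connection specificity, and stimulus-selectivity
    variability; in-silico experiments on perceptual learning and stimulus
    decoding; and a calcium-imaging (dF/F) analysis pipeline with a synthetic
    data generator for validating orientation-preference drift statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    car,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
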