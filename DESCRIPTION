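Package: spikesampler
Title: Spiking Sampling Networks with Hardware-Like Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-stepped simulation of networks of conductance-based leaky
    integrate-and-fire (LIF) neurons that sample from Boltzmann distributions
    over binary random variables, following the theory of neural sampling with
    refractory on-states. Supports the constraints of accelerated analog
    neuromorphic substrates: 4-bit paired excitatory/inhibitory synaptic
    weights, fixed-pattern and trial-to-trial parameter variability, and
    deterministic background noise from recurrent inhibitory random networks.
    Includes in-the-loop wake-sleep training, logistic activation-function
    calibration, and experiment pipelines for target-distribution sampling,
    conditional inference, classification, pattern completion and guided
    dreaming on binary image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
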