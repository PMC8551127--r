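Package: lchazard
Title: Level-Crossing Hazard Rates and First-Passage Times for
    Integrate-and-Fire Neurons with Colored Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps colored (Ornstein-Uhlenbeck) input noise in leaky
    integrate-and-fire neurons to escape noise via the level-crossing
    statistics of the free membrane potential. Provides the upcrossing
    rate of a Gaussian process against a moving boundary (Rice rate),
    the zero-lag pair correlation of upcrossings, local first- and
    second-order decoupling approximations of the hazard rate,
    first-passage-time and interspike-interval densities, the renewal
    integral equation for the population activity of uncoupled
    spiking neurons, exact-update Monte-Carlo simulators for
    validation, and Kolmogorov-Smirnov error sweeps over stimulus
    ensembles.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    deSolve,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
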