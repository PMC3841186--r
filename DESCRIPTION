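Package: affectnet
Title: Discrete-Event Spiking Networks with an Affective Rate Controller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discrete-event simulation of simple spiking artificial neural
    networks embedded in a three-dimensional grid, coupled to an affective
    (neuromodulatory) feedback system that regulates the network firing rate
    by broadcasting threshold changes to every neuron. Includes long-term
    potentiation and depression (LTP/LTD) with per-synapse plasticity
    refractory periods, seeded random network generation, rate-control
    experiment harnesses (settling time, percent overshoot, oscillation
    period, weight histograms), an evolutionary training algorithm over
    network topology and the desired firing rate, and a bang-bang cart-pole
    control benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
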