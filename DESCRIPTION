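Package: snnerp
Title: Spiking Neural Network Modelling of Spatio-Temporal EEG/ERP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling multichannel EEG/ERP recordings with a
    brain-template-mapped three-dimensional spiking neural network.
    Simulates visual-oddball event schedules and class-conditioned ERP
    epochs, encodes each channel into a bipolar spike train by
    threshold-based representation, initialises a small-world reservoir of
    leaky integrate-and-fire neurons positioned on a coarse head template,
    trains it with spike-time-dependent plasticity, summarises the learned
    model through connection-weight and spike-intensity analytics, and
    classifies reservoir activity with a rank-order dynamic evolving
    spiking classifier, evaluated by leave-one-out cross-validation with
    exhaustive grid-search parameter optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
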