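Package: polychrony
Title: Spiking Network Model of the Auditory Pathway with Polychronous
    Group Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical spiking neural network model of the auditory
    pathway (auditory nerve, cochlear nucleus, inferior colliculus,
    primary and belt auditory cortex) built from Izhikevich point
    neurons with axonal conduction delays and mixed
    additive/multiplicative spike-timing-dependent plasticity.
    Includes a synthetic auditory-nerve spike-raster generator with
    temporal and spatial jitter, the per-cell polychronization index
    quantifying reproducible spatio-temporal firing patterns, and a
    decoder-based mutual-information protocol comparing temporal and
    rate codes for stimulus identity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
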