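Package: cocomap
Title: Compressed Connectivity Mapping of Spiking Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates patterned optogenetic stimulation experiments on
    recurrent excitatory/inhibitory Izhikevich spiking networks and
    reconstructs the presynaptic weight vector of every observed neuron by
    L1-regularised (compressive-sensing) regression from far fewer
    stimulation trials than one-cell-per-trial sequential mapping.
    Provides ground-truth network generators (uniform-random and
    Watts-Strogatz small-world digraphs of typed neurons), a biophysical
    simulator with background-noise calibration, synaptic failure,
    off-target stimulation and per-connection propagation latency,
    decay-normalised response extraction, sign-constrained lasso and
    basis-pursuit decoders, recall/precision scoring against ground truth,
    and parameter-sweep orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph,
    readr,
    withr,
    optparse
Config/testthat/edition: 3
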