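Package: somnet
Title: Thalamo-Cortical Spiking Model of Sleep-Dependent Synaptic
    Homeostasis and Memory Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a minimal four-population thalamo-cortical spiking
    network of adaptive exponential integrate-and-fire neurons with
    conductance-based synapses and multiplicative spike-timing-dependent
    plasticity.  The network is trained in unsupervised mode on binary
    visual feature vectors (histogram-of-oriented-gradients codes or
    class-structured synthetic patterns), then driven into deep-sleep-like
    slow oscillations.  The package provides the full experimental
    protocol (training, retrieval, sleep or awake control, classification),
    ablations (cortico-thalamic feedback off), and an analysis battery:
    Up-state segmentation, slow-oscillation frequency, synaptic weight
    block statistics, population correlations, firing-rate redistribution
    and classification accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
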