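Package: hbsync
Title: Synchronization Transitions in Gap-Junction-Coupled Huber-Braun
    Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of Huber-Braun conductance-based neurons
    coupled by gap junctions (electrical synapses) under sleep- and
    wake-like drive currents derived from the Drosophila circadian
    oscillator, and analyses the resulting synchronization transitions.
    Provides generators for regular lattices, rings, rings with random
    long-range connections, rings with controlled connection distance,
    and Watts-Strogatz small-world networks; a fixed-step RK4 network
    integrator with spike detection; spike-phase order parameters
    (pairwise cos^2 statistic S and Kuramoto R) with susceptibilities;
    local field potential synthesis; coupling-strength sweep and
    forward/backward hysteresis protocols; and synthetic spike-train
    fixtures with known synchrony structure for metric validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
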