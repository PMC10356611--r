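Package: ovisearch
Title: Egg-Laying Search Behaviour, Rise-to-Threshold Dynamics and
    Circuit Motifs in Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for Drosophila egg-laying substrate-choice
    experiments: automated search-period detection from locomotor speed,
    substrate-transition statistics with de-rocking, egg-laying-rate curves
    versus time since the last substrate transition with visit-based exact
    binomial confidence intervals, background-subtracted running-mean
    normalised calcium (dF/F) processing with event-triggered averaging and
    slope-to-threshold statistics, spike-train utilities with a GCaMP
    kinetic forward model, and recurrent-motif queries over connectome
    synapse tables.  Includes a value-modulated rise-to-threshold simulator
    that generates synthetic sessions (trajectories, egg events,
    fluorescence, spike trains, synapse tables) with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
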