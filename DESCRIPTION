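Package: chainsim
Title: Spiking Neuronal Chains for Goal-Directed Action Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation of goal-specific neuronal chains in parietal cortex:
    pools of conductance-based leaky integrate-and-fire neurons with kinetic
    AMPA, NMDA (magnesium-blocked) and GABA receptor channels are wired into
    action-specific chains whose burst propagation is gated by simulated
    prefrontal intention signals, sensory feedback and motor corollary
    discharge. Includes the motor, ambiguous-goal ("blind") and visual
    (action recognition) task protocols, a pool-regime calibration sweep,
    and a spike-timing-dependent plasticity rule with activity-dependent
    synaptic efficacy that assembles a feedforward chain from an
    all-to-all network driven by template activity profiles.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
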