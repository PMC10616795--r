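Package: hvephys
Title: Analysis and Simulation of Voltage-Gated Proton Channel Macro-Patch Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing voltage-gated proton (Hv1) channel
    currents from patch-clamp sweep ensembles: Boltzmann fitting of
    current-voltage and tail-conductance-voltage relations, nonstationary
    noise analysis (variance-mean parabola yielding unitary current,
    channel count, maximal open probability and unitary conductance),
    reversal-potential estimation from fast-ramp current families by the
    across-sweep variance minimum, limiting-slope estimation of the
    effective gating charge from slow voltage ramps, and single- and
    multi-exponential activation kinetics. Includes a stochastic
    Markov-chain ensemble simulator of two-state (and sequential
    multi-step) voltage-gated channels with femtosiemens unitary
    conductances, Nernst-governed proton reversal, linear leak and
    Gaussian instrumentation noise, so every estimator can be validated
    by parameter recovery on synthetic data. Reads and writes sweep
    ensembles as Axon-text-style (ATF) or CSV trace files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
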