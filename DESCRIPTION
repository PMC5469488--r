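Package: looplab
Title: Deterministic Simulation of Hard Real-Time Closed-Loop
    Electrophysiology Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic, simulated-time re-creation of the module /
    connector / event / recorder architecture used by hard real-time
    closed-loop electrophysiology platforms. Provides a cycle-accurate
    engine (acquire, execute, drain events, emit), a virtual
    data-acquisition device with per-channel scaling and an external
    high-rate sampler for input/output latency measurement, an HDF5 trial
    recorder with parameter-change logging, real-time benchmark statistics
    with the hard real-time pass rule, a Hodgkin-Huxley point neuron with
    threshold-crossing spike detection and dynamic-clamp leak-conductance
    injection, a spectrogram template detector with RMS gating for
    distorted auditory feedback, an EEG alpha-power feedback controller
    gating 40 Hz stimulation, and seeded synthetic-signal generators
    (trigger trains, birdsong, EEG) so every protocol can be exercised and
    scored without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rhdf5,
    signal,
    stats,
    utils,
    xml2,
    grDevices,
    graphics,
    tools
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
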