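Package: fnsynapse
Title: Fowler-Nordheim Tunneling Synapse Simulation and Memory
    Consolidation Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Behavioral simulation of a differential floating-gate synapse
    whose weight decay is governed by Fowler-Nordheim quantum tunneling, so
    that the decay rate of the stored weight tracks the usage history of the
    device (metaplasticity).  Provides the deterministic device model and its
    closed-form common-mode trajectory, a Poisson single-electron stochastic
    variant for the low-tunneling regime, global plasticity-modulation
    profiles that trade consolidation against graceful forgetting, the random
    binary pattern memory benchmark (analytic and Monte-Carlo retrieval
    signal, noise and SNR, memory lifetime, patterns retained), and a
    continual-learning harness in which every weight of a multi-layer
    perceptron is backed by a synapse instance, with elastic weight
    consolidation baselines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
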