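Package: simqpcr
Title: Stochastic Simulation of Between-Repeat Variability in Real-Time PCR
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A cycle-sequential simulator of real-time PCR amplification
    curves built on a double-log bilinear model of efficiency decline with
    a primer-depletion second phase, together with the variance components
    that drive differences between technical repeats (Poisson template
    sampling, initial-efficiency variation, per-cycle efficiency error,
    primer pipetting, side-reaction primer loss, baseline drift and camera
    noise). Includes quantification-cycle estimation by spline-interpolated
    threshold crossing and by the second-derivative maximum of a
    five-parameter logistic fit, full-process-kinetics recovery of the
    bilinear parameters from observed curves, experiment drivers for
    variance-component and dilution-series studies, plate input/output and
    a command-line generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
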