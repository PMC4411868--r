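Package: spikeNetGLM
Title: Point-Process GLM Functional Connectivity for Spike-Train Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed functional connectivity among simultaneously
    recorded neurons with point-process generalized linear models. Spike
    trains are binned at millisecond timescales, screened for non-Poisson
    firing with a time-rescaling Kolmogorov-Smirnov test, and modeled per
    neuron as Poisson regressions on the immediately preceding spiking
    history of the neighboring population. Significant history coefficients
    form signed and binary connectivity maps that can be summarized
    (connection density, parsimony Q, excitatory/inhibitory balance) and
    compared across task conditions (shared-connection fractions,
    persistence matrices, exact binomial change tests, strength
    correlations). A coupled-GLM network simulator, including the
    elastic-load and neural-driven force laws of a locomotor
    brain-machine-interface paradigm, provides ground-truth data for
    calibration and recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
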