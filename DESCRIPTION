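Package: emuwave
Title: Gaussian Process Emulation, History Matching and Global Sensitivity
    Analysis for Cardiac Mechanics Simulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic surrogate modelling of multi-scale heart
    contraction simulators. Provides Latin hypercube and Saltelli designs of
    computer experiments, a fast 0D time-varying-elastance/Windkessel rat
    left-ventricle simulator mapping eight mechanics parameters to twelve
    pressure/volume features, per-feature Gaussian process emulators with
    polynomial mean functions selected by cross-validation, wave-based
    Bayesian history matching with implausibility-driven NROY space
    reduction, and Saltelli estimation of first-, second-order and total
    Sobol sensitivity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lhs,
    yaml,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
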