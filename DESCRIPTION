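Package: fretBayes
Title: Bayesian Inference of Dissociation Constants and FRET Efficiency
    from Three-Cube FRET Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the in vivo dissociation constant (Kd) and intrinsic
    FRET efficiency of a protein-protein interaction from background-
    corrected three-cube FRET intensity data. Implements a linear spectral
    mixing model with full bleed-through and cross-talk, a bimolecular
    binding equilibrium, a Gaussian measurement-noise likelihood with
    Laplace marginalization of the unknown per-sample fluorophore totals,
    and Metropolis-Hastings posterior sampling with automatic step-size
    tuning, burn-in detection and multi-chain convergence checks. Also
    provides absolute and relative calibration of the photophysical kappa
    constants from donor-only, acceptor-only and tandem-construct samples,
    inference of the apparent FRET efficiency and donor:acceptor ratio,
    a synthetic-data simulator, and an experiment runner for parameter-
    recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
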