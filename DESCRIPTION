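Package: statewave
Title: Hidden Markov Modelling of Dynamic Brain-Network States in
    Electrophysiological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised segmentation of parcellated electrophysiological
    time-series into recurring whole-brain network states using variational
    Bayes hidden Markov models with multivariate Gaussian observation models.
    Supports amplitude-envelope and time-delay-embedded data representations,
    bad-segment detection, symmetric leakage correction, state temporal
    statistics, task-evoked occupancy inference with sign-flip max-statistic
    permutation GLMs, state-weighted multitaper spectra and coherence,
    non-negative matrix factorisation of spectra into data-driven frequency
    modes, and HMM-based time-frequency reconstruction. Ground-truthed
    synthetic data generators make the whole pipeline testable without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    mclust,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
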