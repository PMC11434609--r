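Package: sleepHMM
Title: Variational-Bayes Gaussian Hidden Markov Modelling of Whole-Night
    Sleep Brain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data-driven characterization of whole-night sleep from
    multichannel brain time series (e.g. ROI-averaged fMRI signals). Fits
    a variational-Bayes Gaussian hidden Markov model to PCA-reduced,
    standardized, concatenated recordings; selects the number of brain
    states at the first local minimum of the variational free energy;
    summarizes states by fractional occupancy, mean lifetime and
    sleep-stage distribution with winner-takes-all stage assignment;
    clusters the state transition matrix into modules by directed
    (Leicht-Newman) spectral modularity; back-projects state means and
    covariances to region space for activation and functional-connectivity
    maps; and generalizes a frozen model to a held-out recording night.
    Includes a synthetic-data generator producing hypnogram-structured
    multi-state Gaussian time series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
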