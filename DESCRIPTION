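Package: neurotau
Title: Multi-Timescale Structure of Single-Neuron Spiking Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intrinsic timescales of single neurons from the
    autocorrelation of binned spike counts by mixture-of-exponentials
    fitting with BIC model selection, tests power-law scaling of timescale
    populations (KS-minimizing cutoff maximum likelihood, bootstrap
    goodness of fit, normalized log-likelihood ratios against exponential
    and log-normal alternatives), quantifies task-variable selectivity
    with a condition-combined Mann-Whitney U statistic under a
    block-restricted permutation null, relates timescales to voxel-level
    anatomical features by ridge regression with phase-randomized spatial
    surrogates, and reproduces the linear (Ornstein-Uhlenbeck) and
    nonlinear (heavy-tailed connectivity) recurrent-network mechanisms
    that generate power-law timescale distributions. Includes synthetic
    generators for doubly stochastic spike trains, task trial tables with
    block structure, and smooth voxel feature fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
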