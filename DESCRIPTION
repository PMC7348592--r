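Package: fconnectome
Title: Graph-Theoretical Group Analysis of Resting-State Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of resting-state functional brain
    networks: temporal cleaning of regional time series (detrending, bandpass
    filtering, nuisance regression), head-motion quality control (framewise
    displacement, scrubbing, exclusion rules), sparsity-thresholded binary
    graph construction from Pearson connectivity matrices, small-world and
    efficiency metrics normalized against degree-preserving rewired null
    ensembles, covariate-adjusted permutation tests, the network-based
    statistic (NBS) for component-level inference on edgewise differences,
    purity-index assignment of anatomical nodes to functional systems,
    brain-behavior partial correlation, and stepwise linear discriminant
    classification with leave-one-out cross-validation. Includes a seeded
    synthetic two-group cohort generator with modular (block) covariance so
    the full pipeline can be exercised and calibrated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    pracma,
    pROC,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
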