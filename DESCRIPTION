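Package: netprog
Title: Brain Network Progression Along Healthy-Brain Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models MRI connectome progression in unilateral mesial temporal
    lobe epilepsy as a function of healthy-brain architecture. Provides
    edge-wise age normalization of functional and structural connectomes
    fitted on controls, healthy-brain distance topologies (streamline
    length, structural and functional connectivity, resting-state-network
    gradient), a permutation-subsampled Mahalanobis deviation statistic of
    hippocampal networks with Ledoit-Wolf shrinkage covariance, a
    three-criterion distance-gradient hypothesis test with duration-group
    analysis, and a hybrid functional-structural connectome ICA linking
    whole-brain change to duration of disease. Includes a synthetic-cohort
    generator with planted ground truth so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
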