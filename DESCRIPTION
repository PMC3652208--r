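Package: iemmc
Title: Unsupervised ECG Arrhythmia Detection by Immune-Evolutionary
    Maximum-Margin Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, single-lead ECG arrhythmia detection pipeline:
    a wavelet-transform adaptive filter (depth-selected discrete wavelet
    approximation plus LMS adaptive cancellation of the low-frequency
    reference) for baseline-wander and high-frequency noise removal;
    rule-based delineation of R, Q, S, P and T landmarks with refractory
    and search-back logic; nine time-domain beat features spanning two
    succeeding cardiac periods; and, at its core, square-loss
    maximum-margin clustering solved by a clonal-selection immune
    evolutionary algorithm with a least-squares SVM inner solver, class
    balance constraint, and bias/label refinement. Includes seeded
    synthetic ECG and feature-cluster generators, cluster-to-class
    evaluation metrics, and a K-means baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
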