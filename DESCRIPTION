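Package: dfcStates
Title: Dynamic Functional Connectivity State Discovery and Group Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for time-varying functional-connectivity analysis of
    independent-component (IC) time courses from resting-state fMRI.
    Computes sliding-window Pearson correlation features, discovers
    recurring connectivity states by k-means clustering with elbow-based
    model selection, derives per-subject state-occupancy features,
    classifies two groups of subjects with a cross-validated decision
    tree, and performs state-, window- and connection-level group
    statistics with Benjamini-Hochberg false-discovery-rate control.
    Includes a Markov-switching multivariate Gaussian cohort simulator
    providing ground-truth states for validation, and utilities for
    assigning IC spatial maps to resting-state network templates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    rpart,
    RNifti,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification, Clustering,
    TimeCourse, Network
RoxygenNote: 7.3.3
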