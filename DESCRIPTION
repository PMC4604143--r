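Package: hbclass
Title: Two-Stage Supraventricular/Ventricular Heartbeat Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage classifier of supraventricular (SVB) and ventricular
    (VB) heartbeats for two-lead ambulatory ECG. Stage 1 fast-assigns beats to
    the SVB class by correlation against a continuously averaged reference
    template under an adaptive correlation threshold; non-matched beats receive
    20 time-domain morphology and rhythm features, expanded to 210 second-order
    interaction terms, and a refined Stage-2 decision by one of four trainable
    classifiers: k-means cluster with nearest-centroid labelling, empirical
    percentile fuzzy, linear discriminant analysis with class priors, and a
    classification tree with deviance, Gini or twoing splitting and
    misclassification-cost pruning. Includes the iterative forward
    feature-selection training protocol optimising Mean(Se,PPV), hyperparameter
    sweeps, sensitivity/specificity/positive-predictivity evaluation under
    AAMI EC57 beat groupings, and a synthetic ECG and feature-table generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
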