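Package: seizclust
Title: Cluster-Based Feature Extraction and Classifier Benchmarking for
    EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a seizure-detection workflow for single-channel EEG
    segments: reading and writing the Bonn ASCII segment dialect, seeded
    two-class synthetic EEG generation, cluster-based data reduction with two
    learning-based (k-means/k-median, fuzzy c-means) and four bio-inspired
    (cuckoo search, dragonfly, firefly, modified firefly) clustering
    algorithms sharing a within-cluster distance objective, entropy-based
    separability analysis (approximate, sample and Shannon entropy), a
    registry of ten classifiers with an MSE-versus-iterations hyperparameter
    search, and stratified k-fold benchmarking with sensitivity, specificity
    and accuracy reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    MASS,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
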