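Package: riboblock
Title: Riboswitch Family Classification from Sequential Block Locations
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free discovery of family-specific sequential blocks in
    riboswitch RNA families and block location-based feature extraction (BLBFE)
    for classifying sequences into families. Provides the sequential block
    finding (SBF) search (exhaustive short-motif enumeration, positional
    prevalence filtering, redundancy elimination), conversion of sequences
    into integer vectors of 1-based block start locations, four classifiers
    (regularised linear discriminant analysis, probabilistic neural network,
    decision tree, k-nearest neighbours) under stratified V-fold
    cross-validation, multiclass confusion-matrix performance measures
    (accuracy, sensitivity, specificity, f-score, correct classification
    rate) with macro averaging, a synthetic family generator with planted
    location-constrained motifs for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    class,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
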