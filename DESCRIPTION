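Package: fuzzrank
Title: Fuzzy Rank-Based Ensemble Fusion for Misinformation Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a fuzzy rank-based ensemble of
    text classifiers for health-misinformation detection. Per-classifier
    confidence vectors are transformed into fuzzy ranks with a reparameterized
    Gompertz function and fused, per test case, into a final decision via
    rank sums weighted by complement confidence factors. The package also
    provides the surrounding corpus pipeline (cleaning, deduplication,
    topic-keyword filtering, source-label harmonization, stratified
    splitting), descriptive text profiling (keyword occurrence, polarity and
    subjectivity bucketing), a unigram TF-IDF plus linear SVM baseline with
    cross-validation, an analytic transformer parameter counter, standard
    evaluation metrics (including Mann-Whitney AUC), and synthetic-data
    generators that emulate an imbalanced two-class corpus and correlated
    multi-classifier probability outputs so every component is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
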