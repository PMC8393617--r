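Package: capdet
Title: Cyclic Alternating Pattern Phase Detection from Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection of cyclic alternating pattern (CAP) phase A versus
    phase B activity in NREM sleep EEG. Designs orthogonal wavelet filter
    banks with minimum root-mean-square bandwidth by convex optimization and
    spectral factorization, decomposes epochs into dyadic subbands, extracts
    wavelet-entropy and Hjorth features, applies Terzano-style CAP sequence
    rules to annotations, and evaluates ensemble tree, SVM, k-nearest
    neighbour and logistic classifiers with stratified cross-validation.
    Includes a synthetic sleep-EEG generator, an EDF codec and a command-line
    interface, so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    pracma,
    rpart,
    randomForest,
    xgboost,
    e1071,
    class,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
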