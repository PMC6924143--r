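Package: odnscreen
Title: Sequence-Based Screening of CpG Oligodeoxynucleotides for Mouse
    TLR9 Agonist Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts mouse Toll-like receptor 9 (mTLR9) agonist activity of
    single-stranded CpG oligodeoxynucleotides (ODNs) from sequence alone.
    Provides positional k-mer binary fingerprints, motif-distance descriptors,
    2D graphical (rigid-body) sequence features, leakage-aware feature
    filtering (near-zero variance, linear combinations, correlation),
    imbalance-aware repeated down-sampling, an ensemble of random-forest
    classifiers with consensus prediction and ranking of candidate ODNs,
    confusion-matrix performance metrics, Mann-Whitney motif-effect
    statistics, and a seeded synthetic ODN generator with planted motif
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
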