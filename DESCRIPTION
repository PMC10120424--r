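Package: remscore
Title: Imbalance-Aware Ensemble Scoring of Noncoding Regulatory Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and scoring framework for probability-like pathogenicity
    scores of noncoding single-nucleotide variants under extreme class
    imbalance. Implements the hyperSMURF scheme (SMOTE oversampling of the
    pathogenic minority, non-overlapping partitioning and subsampling of the
    proxy-benign majority, one random forest per partition, averaged
    probabilities), cytogenetic-band-aware stratified cross-validation with
    unbiased held-out scores, per-feature missing-value imputation policies,
    precision-recall / ROC / F-beta threshold calibration, Gini feature
    importance aggregation, tabix-indexed prescored score tracks with
    cross-validated score substitution, and a synthetic-data generator that
    emulates the imbalance, band clustering and missingness structure of real
    regulatory-variant training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ranger,
    jsonlite,
    yaml,
    optparse,
    vcfR,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
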