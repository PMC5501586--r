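Package: ctdnascreen
Title: Power Analysis and Classification for ctDNA Copy-Number-Based
    Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico evaluation toolkit for cancer screening from
    copy-number variants (CNVs) in circulating tumor DNA (ctDNA).
    Provides synthetic generators for binned cell-free DNA read counts
    and tumor segmentation cohorts; preprocessing of 10 kb bin counts
    (minimum-covariance-determinant outlier masking, LOESS-style GC
    correction); negative-binomial modelling of bin counts with a
    theoretical limit-of-detection engine over sequencing depth, ctDNA
    fraction and copy change; conversion of tumor segmentations into
    coarse ctDNA-detectable copy profiles on 5 or 100 Mb genome grids
    with five-level symbolic discretisation; and cancer detection /
    tissue-of-origin classification via a modified Hamming distance,
    k-nearest-neighbour voting and cross-validated random forests, with
    ROC and misclassification-similarity reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    MASS,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
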