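Package: POSelect
Title: Proportional Overlapping Score Feature Selection for Two-Class
    Expression Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Filter-based gene selection for binary-class gene expression
    matrices built on overlap analysis of per-class robust core expression
    intervals. Computes interquartile-range core intervals per gene and class,
    binary gene masks encoding unambiguous sample classification, the
    proportional overlapping score (POS) combining overlap length, overlapped
    sample count and class-proportion balance, relative dominant class
    assignments, a greedy minimum-covering gene subset, and a final round-robin
    ranked selection. Includes a selection-stability index over cross-validation
    subsamples, a synthetic two-class data generator with planted informative,
    partially overlapping, scale-difference and noise genes, a Wilcoxon
    rank-sum baseline selector, and a cross-validated benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    randomForest,
    e1071,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: FeatureExtraction, Classification, GeneExpression, Microarray
RoxygenNote: 7.3.3
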