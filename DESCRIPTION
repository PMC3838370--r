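Package: FisherSum
Title: Detection of Differentially Expressed Patient Subgroups in
    Two-Group Omics Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Univariate statistics for detecting patient subgroups with
    differential expression in case-control omics studies.  Implements the
    FisherSum score (a weighted exceedance sum built on the idea of Fisher's
    exact test) together with six established comparators (outlier sum,
    outlier-robust t, a PADGE-like percentile score, excess kurtosis,
    Bartlett's test, one-sided t-test), a mixture-model simulator for three
    subgroup scenarios with a composite null design, a likelihood-ratio
    performance oracle, and a ROC/AUC benchmarking harness for method
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
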