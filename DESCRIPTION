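Package: virionPred
Title: Phage Virion Protein Prediction by Two-Step g-Gap Dipeptide Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies phage virion (structural) proteins from amino-acid
    sequence alone. Sequences are encoded as g-gap dipeptide composition
    vectors (g = 0..9), features are ranked per gap by the one-way ANOVA F
    statistic and pruned by incremental feature selection with a
    cross-validated RBF-kernel support vector machine, the ten per-gap optimal
    subsets are fused, re-ranked by minimal-redundancy-maximal-relevance
    (mRMR) mutual information, and a second incremental pass locates the final
    model. Includes confusion-matrix metrics (Sn, Sp, Acc, Mcc), ROC/auROC, a
    synthetic benchmark generator with planted dipeptide signals, and a
    command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
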