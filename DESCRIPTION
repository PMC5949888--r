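Package: idrscreen
Title: Growth-Selection Screen Analysis for Functional Disordered Regions
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled growth-selection screens that assay
    short disordered peptides (for example transactivation domains fused to a
    truncated transcription factor). Covers the full computational phase of
    such a screen: a synthetic-screen simulator with planted ground truth,
    read preprocessing (merging, quality filtering, demultiplexing,
    dereplication, greedy centroid clustering, mapping), robust-regression
    growth estimation with stop-codon-calibrated functional thresholds, a
    146-feature peptide encoding framework (compositions, degenerate
    mini-motifs, 9aaTAD, physicochemical scales), imbalance-aware machine
    learning (penalized logistic regression, gradient-boosted trees, a
    stacked ensemble) with relative feature-importance tables, and
    substitution-tolerance analysis for deep mutational scans of wild-type
    domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    MASS,
    glmnet,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    withr,
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
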