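Package: pretimeth
Title: Per-Locus Logistic Models for Methylation Array Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds one regression model per CpG locus to expand 450K-style
    DNA methylation beta-value matrices to EPIC-style coverage. For every
    target ("model") locus the single most co-methylated feature locus
    across training samples is selected by Pearson correlation (optionally
    together with the nearest neighbouring locus and the locus with the
    most similar flanking sequence, summarized by 340 k-mer frequencies),
    an independent logistic (or ordinary least squares) regression is
    fitted on beta values, and five-fold cross-validated RMSE stratifies
    each model into accuracy categories. Accuracy-filtered predictions
    feed differential methylation calling (Welch's t-test with
    Benjamini-Hochberg correction) and promoter-based differentially
    methylated gene aggregation. A self-contained synthetic-fixture
    generator with planted co-methylation structure, noise tiers,
    missingness and group effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
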