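Package: dropshift
Title: Dropout-Driven Discordance Between Bulk and Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and models why paired bulk and droplet single-cell
    RNA-Seq profiles of the same samples disagree. Builds pseudo-bulk
    profiles and per-gene dropout rates, fits a five-parameter logistic
    dropout-versus-bulk-expression curve by minimizing the
    Kolmogorov-Smirnov statistic of its residuals, calls discordant genes
    from scaled residuals, ranks technical factors (expression, transcript
    integrity, gene architecture, mappability) by machine-learned
    permutation importance, and locates pathway-level enrichment of
    discordance with preranked gene-permutation GSEA. Includes a synthetic
    paired-data generator with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    mclust,
    nnet,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    fgsea,
    Biostrings
Config/testthat/edition: 3
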