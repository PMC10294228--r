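Package: revsig
Title: Drug-Resistance Signatures and Signature-Reversal Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-arm drug-resistance gene signatures from a
    neoadjuvant expression cohort stratified by receptor subtype and
    treatment, selecting the log2 fold-change cutoff that maximizes the
    Matthews correlation between k-means sample clusters and clinical
    response labels derived from residual cancer burden. Signatures are
    profiled with preranked gene-set enrichment and scored against a drug
    perturbation compendium with a bidirectional Kolmogorov-Smirnov reverse
    gene expression score (RGES), assessed by a permutation null with
    Benjamini-Hochberg correction. Includes a synthetic-data generator
    that plants resistance signatures, a reverser and a mimicker drug, so
    the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
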