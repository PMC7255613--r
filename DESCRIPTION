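Package: deepsav
Title: Missense Variant Pathogenicity and Gene Mutation-Severity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores single-amino-acid variants (SAVs) for pathogenicity with a
    deep 1-D convolutional neural network over per-position sequence, structure
    and functional features (the DeepSAV score), optionally augmented with
    population allele frequency and gene-level constraint features (+PG), and
    aggregates variant scores into a gene-level mutation-severity measure, the
    GTS (Gene Tolerance of rare SAVs) score. Includes alignment profile and
    conservation estimation, a 90-feature positional encoder with 21-residue
    windows and feature-group ablation masks, stratified cross-validation with
    ROC AUC evaluation, log2 odds enrichment of positional properties in
    variant subsets, gene-set analyses (Z-scoring, correlation-distance
    complete-linkage clustering, three-way overlaps, disease-class
    observed/expected ratios), and a synthetic-data generator that emulates
    conserved and variable alignment columns, functional-site annotations and
    a rare-dominated allele-frequency spectrum for fully self-contained tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
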