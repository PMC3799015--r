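Package: dcmature
Title: Cross-Condition Meta-Analysis of Dendritic Cell Maturation
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cross-condition, cross-species
    transcriptome meta-analysis of dendritic cell (DC) maturation.
    Implements expression filtering with complete-linkage hierarchical
    clustering and principal component analysis, duplicate-robust
    differential expression with an additive-plus-proportional error
    model and Benjamini-Hochberg control, three-subset Venn
    partitioning, a gene set enrichment analysis (GSEA) engine with
    weighted running-sum scores, gene-set permutation nulls and
    leading-edge extraction, a cross-species leading-edge frequency
    consensus producing a core maturation signature, and promoter
    transcription-factor-binding-site enrichment combining TRAP
    biophysical affinities with rank-cutoff-maximised hypergeometric
    statistics. A synthetic-data module generates multi-condition
    studies and promoter sequences with planted ground truth so every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    ape,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
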