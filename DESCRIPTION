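Package: cleavecat
Title: Discovery and Characterization of Long Non-Coding RNAs from
    Assembled Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering novel long non-coding RNAs
    (lncRNAs) from transcript assemblies of single-cell RNA-seq data, modelled
    on catalog-building workflows for mouse cleavage-stage embryos. Implements
    cuffcompare-style class-code classification against reference annotation,
    a two-assembler/two-sample consensus rule, ROC-learned read-coverage and
    integrity filtering, splice-motif strand inference, an ORF-feature coding
    potential score with a pluggable protein-homology oracle, neighbour-gene
    and bidirectional-promoter analyses, Jensen-Shannon temporal specificity
    scores, and a from-scratch signed weighted co-expression network
    (soft-threshold adjacency, topological overlap, average-linkage clustering
    with a simplified dynamic tree cut, module eigengenes, kME and
    module-trait statistics). A synthetic-data module generates every pipeline
    input with planted ground truth so the whole analysis is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
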