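Package: mirstack
Title: Small RNA-Seq Preprocessing, miRNA Quantification and Consensus Novel
    miRNA Discovery from Read Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for small RNA sequencing analysis in
    endothelial lineage cells and similar three-condition designs: adapter
    filtration and read collapsing with per-rule accounting, k-mer seed
    alignment of collapsed tags against mRNA, miRNA and genome references,
    multi-mapping-aware RPM quantification of known miRNAs, consensus novel
    miRNA discovery from genomic read stacks with weighted base-pair
    maximization hairpin folding, expression pattern classification across
    three cell types, exact small-sample rank tests, and a fully seeded
    synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
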