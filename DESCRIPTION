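Package: lncnet
Title: Cell-Type Expression and Cross-Species Co-Expression Network
    Conservation of Sponge Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for long non-coding RNA (lncRNA) expression in
    sponges. Provides sample quality filtering, median-of-ratios normalization,
    a native negative-binomial Wald test for pairwise differential expression
    with Benjamini-Hochberg correction, cell-type enrichment calls and
    expression-quartile binning; classification of lncRNAs by genomic context
    (intergenic, cis-antisense exon overlap, genic-other) with exact
    Mann-Whitney and Fisher tests; correlation-threshold co-expression network
    construction over developmental stages with lncRNA hub modules; and calling
    of putatively conserved module pairs between two species from a
    protein-coding homology table. A synthetic two-species data generator with
    planted modules, differential genes and annotation classes makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
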