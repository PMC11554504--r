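Package: retronet
Title: Interactome Connectivity and the Structural and Regulatory
    Evolution of Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the connectivity of protein-coding genes in a
    directed human-interactome model to two evolutionary rate metrics:
    structural (dN/dS) and regulatory (retroelement-linked enrichment of
    regulatory features around transcription start sites, the NGRE/NPII
    scores). Provides a synthetic-data generator with controllable
    rank-correlation structure (Gaussian copula), interval-based feature
    mapping into TSS windows, enrichment scoring with weighted
    aggregation across profiles, interactome assembly from pathway graph
    collections (complex-node expansion, merging, pruning, two
    connectivity modes), gene-neighborhood pathway construction with a
    size/coverage/Jaccard filtering cascade, and gene- and pathway-level
    Spearman correlation and inheritance-type analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
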