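Package: VQFamily
Title: Genome-Wide Analysis of VQ Motif-Containing Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genome-wide characterisation of plant VQ
    motif-containing protein families. Locates and classifies the conserved
    VQ decamer (consensus FxxxVQxLTG) in protein sequences, summarises
    family composition, computes gene-structure statistics (intron counts,
    copy-number groups) from gene models, derives protein physicochemical
    properties (molecular weight, isoelectric point), builds neighbor-joining
    phylogenies with bootstrap supports from protein alignments, scans
    promoters for stress-related cis-regulatory elements, profiles tissue and
    drought-stress expression including qPCR 2^-ddCt analysis, and constructs
    Pearson-threshold VQ-WRKY co-expression networks. Ships a curated table
    of the 61-member maize (Zea mays) ZmVQ family and seeded synthetic-data
    generators with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Phylogenetics, GeneExpression,
    NetworkInference, Transcriptomics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
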