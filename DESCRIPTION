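Package: TEtrap
Title: Characterization of Actively Expanding Transposons as Young piRNA Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize transposable elements that are actively
    expanding in a genome and behaving as young piRNA clusters. Implements
    novel-insertion discovery from long-read structural-variant breakends
    (junction pairing under a maximum-gap, orientation-consistency rule),
    transitive homology grouping of insert sequences with an activity ranking
    based on old/new genomic area, piRNA ping-pong and phasing signature
    z-scores, SNP-based attribution of small RNAs to individual element
    copies, insertion-site genotyping from long reads, and RPKM/ChIP
    enrichment quantification. A synthetic-data module generates toy genomes
    carrying multi-copy LTR elements, long reads, breakends and small-RNA
    libraries with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transposon, SmallRNA, StructuralVariation, Sequencing, Software
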