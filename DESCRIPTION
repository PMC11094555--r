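Package: GeneNeighborhoods
Title: Extraction, Alignment-Based Comparison and Visualization of
    Microbial Gene Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring the genomic context of genes in bacterial
    and archaeal genomes. Extracts gene neighborhoods within a fixed window
    around anchor genes from GFF3 or GenBank annotation (excluding genes
    that cross the window edges), compares neighborhoods with a
    Smith-Waterman-style local alignment over per-gene annotation label
    sets (KEGG, Pfam, TIGRFAM or custom namespaces), orders them by
    average-linkage hierarchical clustering, filters tabular homology hit
    lists by E-value, identity and bidirectional coverage, and renders
    deterministic multi-track SVG figures with frequency-based gene
    coloring. Includes seeded generators of synthetic genomes and hit
    tables so the full workflow runs offline, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rcpp,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
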