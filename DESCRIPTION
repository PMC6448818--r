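Package: utrmotif
Title: Weight-Matrix Scanning and Scrambled-Control Enrichment for UTR
    Cis-Regulatory Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds position weight matrices from aligned RNA motif
    instances, extracts stitched 5'UTR/CDS/3'UTR sequences from a genome
    plus GFF3/GTF annotation in transcript orientation, scans regions for
    full and bipartite ("split") motif occurrences by exact, degenerate
    IUPAC or log-odds matrix matching, and tests region-wise enrichment
    against column-permuted (scrambled) control motifs with an empirical
    p-value. Includes a seeded synthetic-transcriptome generator with
    planted-motif truth tables so every stage of the pipeline can be
    validated without external data. Motivated by the analysis of an
    11-nt cis-regulatory element (the D3U-box) enriched in vertebrate
    3' UTRs and recognised by antagonistic RNA-binding proteins.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
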