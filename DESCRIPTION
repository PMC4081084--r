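Package: peakscape
Title: Downstream Analysis of Transcription-Factor ChIP-seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the downstream analysis of transcription
    factor ChIP-seq peak calls: nearest-gene annotation with strand-aware
    signed TSS distances, genic-location and TSS-proximity classification,
    stratification of peaks by target-gene expression (RPKM cutoff),
    TSS-distance histograms, IUPAC consensus scanning of core-promoter
    elements in summit-centered windows, enrichment tests (Pearson chi-square,
    Wilcoxon rank-sum, Wilson intervals), and peak co-occupancy overlap
    matrices against external peak sets within a gap tolerance. Includes a
    synthetic-data generator with a ground-truth ledger so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
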