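Package: thapscan
Title: Sort-Seq Deep Mutational Scanning and Regulatory Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for FACS sort-and-sequence deep mutational
    scanning of transcription-factor activity, built around the THAP1/PSMB5
    reporter screen design: site-saturation mutagenesis library design with
    segment tiling and codon assignment, a generative simulator of the sorted
    screen (library composition, infection, fluorescence gating, per-bin
    sequencing reads), amplicon read matching and counting, wild-type-anchored
    enrichment scoring with replicate filters and position-by-amino-acid
    activity matrices, plus companion analyses: co-essentiality mining of gene
    effect matrices, THABS (TNNNGGCA) promoter motif scanning, minimal
    differential-expression calling with control discounting, ChIP-occupancy
    intersection for direct-target calling, and delta-delta-Ct quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    pheatmap,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
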