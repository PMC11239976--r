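Package: germchrom
Title: Chromatin Accessibility and Expression Statistics for the Embryonic Drosophila Germline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for single-cell multiome profiling of the Drosophila
    embryonic germline. Computes per-cluster chromatin read-distribution
    scores from scATAC fragment files (end-to-start accessibility, TSS
    enrichment, fraction of reads in peaks, fragment-size distributions),
    megabase-windowed accessibility indices and female-to-male dosage
    ratios, zygotic-activation gene selection by negative-binomial
    differential expression, sex expression ratios by chromosome,
    germline-versus-soma transcription bias with strand-aware promoter
    extraction, motif-site accessibility indices with PCA over clusters,
    and per-nucleus histone intensity normalization. A synthetic-data
    generator with known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
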