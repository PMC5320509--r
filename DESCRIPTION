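Package: ernakit
Title: Identification and Differential Analysis of Transcribed Enhancers
    from Strand-Specific RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify enhancer RNAs (eRNAs) from strand-specific
    total RNA-seq: extended genic-region masking with opposite-strand read
    filtering, Poisson-background peak detection of transcribed intergenic
    regions, SICER-style H3K27ac island calling and island-based vetting of
    the eRNA catalogue, median-of-ratios normalisation with a negative
    binomial Wald test for two-condition differential eRNA expression,
    super-enhancer and RNA polymerase II peak integration, and a resampling
    Z-score statistic for transcription-factor motif enrichment in eRNA
    sequence. Includes a synthetic two-condition dataset generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    MASS,
    stats,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
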