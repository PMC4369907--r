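Package: riceHNT
Title: Cross-Line Transcriptome Analysis of Rice Under High Night Temperature
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested reimplementation of the quantitative workflow used to
    find rice transcripts that respond differently to high night temperature
    in a heat-tolerant (XN0437T) versus a heat-sensitive (XN0437S) line at
    the early milky stage of grain filling: FASTQ read quality filtering,
    FPKM normalization of fragment counts, per-line differential-expression
    calling at p <= 0.05 and |log2 fold change| >= 1, cross-line expression
    pattern classification, Relative Fold Change (RFC) selection of high
    night temperature response transcripts at RFC >= 2, per-sample
    read/mapping/assembly summary statistics (including N50), and qPCR
    validation via the 2^-ddCt method together with the grain-plumpness
    phenotype score. A negative-binomial count simulator with planted
    cross-line effect classes, a paired-end read simulator, and a Ct-value
    simulator provide inputs with known ground truth so every stage is
    testable without the original sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
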