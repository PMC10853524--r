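Package: excisr
Title: Genome-Wide Excision Repair Profiling from XR-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nucleotide excision repair genome-wide from XR-seq
    (excision repair sequencing) read alignments. Read densities are
    normalized against simulated background reads matched for total count,
    read-length distribution and damage-site dinucleotide content, removing
    sequence-composition bias from the repair signal. Provides strand-specific
    metagene repair profiles over genes and flanks, per-gene transcribed
    versus non-transcribed strand (TS/NTS) repair ratios and their
    correlation with expression, chromatin-state stratified repair with
    pairwise Welch tests, read-length and positional dinucleotide QC for
    excision products, a fully parameterised synthetic dataset generator for
    validation, and bedGraph track export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
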