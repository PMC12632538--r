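Package: repeatmosaic
Title: Somatic Repeat-Length and Methylation Mosaicism from Targeted Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies somatic mosaicism at tandem-repeat disease loci
    (FMR1-type CGG, FXN-type GAA, RFC1-type AAAAG expansions) from targeted,
    amplification-free long reads. Provides flank-anchored per-read allele
    sizing with fuzzy anchor matching, per-CpG and per-read 5mC methylation
    scoring from MM/ML modified-base tags, allele classification and
    per-region mosaicism summaries, the TP-PCR/CE instability (expansion)
    index from electropherogram peak tables, and a seeded simulator of
    reads and capillary-electrophoresis traces with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
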