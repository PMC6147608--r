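Package: crmscan
Title: Combinatorial Prediction of Cis-Regulatory Modules from ChIP-seq,
    Open Chromatin and Motif Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate cis-regulatory modules (CRMs) genome-wide by
    intersecting transcription-factor ChIP-seq peak sets, open-chromatin
    (FAIRE) peaks, and position-weight-matrix motif hits, then assigning each
    surviving anchor peak to its nearest annotated transcript. Provides a
    native PWM scanner with percent-of-maximum score thresholds, a
    bedtools-style interval algebra with full-containment ("-F 1.0")
    report-A/unique intersection semantics, readers and writers for FASTA,
    BED6, ENCODE narrowPeak, minimal GTF and JASPAR/MEME/TSV motif matrices,
    and a seeded synthetic-genome generator that plants motif instances with
    known ground truth so that every pipeline stage can be verified without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
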