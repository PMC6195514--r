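Package: peakcalibre
Title: Expression-Guided Calibration and Annotation of Transcription-Factor ChIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of transcription-factor ChIP-seq peak calls in
    hematopoietic cells: blacklist and fold-enrichment quality filtering of
    narrowPeak calls, closest-TSS gene association and genomic-category
    annotation, expression-guided calibration of the minimal peak
    fold-enrichment threshold by a hypergeometric (one-sided Fisher) sweep,
    position-weight-matrix motif scanning with ETS/RUNX/IRF class assignment,
    cross-cell-line peak-set comparison, and chromatin-state assignment
    against a 15-state segmentation. Includes a fully seeded synthetic-data
    generator that plants ground truth (motif classes, fold-enrichment /
    expression coupling, cross-set overlap, chromatin-state bias) so the whole
    pipeline is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
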