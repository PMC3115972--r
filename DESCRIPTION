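Package: varfunnel
Title: Targeted Capture Design and Multiplexed SNV Candidate Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for up-front filtering of sequence-variant biomarker
    candidates from multiplexed targeted capture experiments. Implements
    differential-staining candidate selection from antibody tissue-profiling
    tables, capture target-region design (coding exons, UTRs and promoter
    windows, padded to a minimum length and fused on overlap), barcode
    demultiplexing, pileup-based SNV calling with an allele-fraction
    threshold, synonymous/non-synonymous effect annotation, novelty filtering
    against a known-variant catalog, sample-recurrence counting, and a
    verification funnel with per-sample coverage and per-base variation-rate
    reports. Ships a deterministic synthetic-data generator (genome, gene
    models, staining table, planted heterozygous variants, barcoded reads
    with a systematic-error process) whose manifest acts as a truth oracle
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
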