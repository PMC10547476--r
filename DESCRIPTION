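Package: isletwave
Title: Islet Calcium Oscillation Waveform Analysis and Proteome-GWAS Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes pancreatic-islet calcium oscillation traces into waveform
    parameters (period, active/silent/pulse durations, plateau fraction) with
    explicit plateau and silent edge-case codes, summarises each trace segment's
    power spectrum by its top two component frequencies, integrates animal-level
    calcium parameters with a protein abundance matrix through Z-score Pearson
    correlation and candidate flagging, and nominates candidate genes by
    assigning glycemic-trait GWAS SNPs to genes via flanking windows and
    promoter-capture HiC loop contacts. Includes a synthetic-data generator that
    emulates the strain-by-sex cohort structure, stimulus-segment schedule, and
    planted protein-parameter correlations the analysis assumes, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
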