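Package: TriadSeq
Title: Coordination Analysis of Transcription Rate, mRNA Abundance and
    Translation Activity Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates matched GRO-seq (transcription rate), RNA-seq
    (mRNA abundance) and polysome-profiling (translation activity)
    gene-level profiles. Converts HTSeq-style count tables to RPKM,
    filters expressed genes, fits pairwise log-log regressions with a
    two-slope comparison test, computes the mRNA stability index
    log2(RA/TR) and translation index log2(TA/RA), builds a permutation
    null for their association, quantifies the dispersion increase from
    transcription to translation, stratifies the index coupling by mRNA
    UTR proportion, and compares index-space distances across
    gene-similarity strata. Ships a calibrated synthetic-data generator
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, Regression, GeneExpression
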