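Package: peakstate
Title: Integrative Expression-Array and ChIP-Seq Classification of
    Transcription-Factor Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative regulatory-genomics pipeline that identifies
    direct transcription-factor target genes by combining replicated
    expression-array contrasts with ChIP-Seq binding data. Provides
    differential-expression calling with Benjamini-Hochberg adjustment and
    gene-level reconciliation of multi-probe-set genes, a simplified
    input-normalised binomial peak caller, promoter/intron peak-to-gene
    assignment, a six-class joint deregulation-by-binding target
    classification with full Venn bookkeeping, normalised rank-shift motif
    overrepresentation over position weight matrix collections,
    delta-delta-Ct qPCR quantification, and a synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
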