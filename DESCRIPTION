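Package: lncsig
Title: Calling and Characterizing a Regulatory T Cell lncRNA Signature
Version: 0.1.0
Authors@R: person("lncsig", "maintainers", email = "lncsig@example.org",
    role = c("aut", "cre"))
Description: Tools to call a core long non-coding RNA (lncRNA) expression
    signature of regulatory T cells (Tregs) from bulk RNA-seq counts and to
    test whether that signature is shaped by a transcription factor. The
    pipeline covers negative-binomial differential expression with
    median-of-ratios normalization, positional classification of lncRNA
    relative to protein-coding genes, ChIP-seq peak colocalization
    enrichment, knockout-reversal analysis, conserved-region scanning in
    pairwise alignments, and 2^-ddCt qPCR quantification. A synthetic-data
    module plants every structure the analysis assumes so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
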