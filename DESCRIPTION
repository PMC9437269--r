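Package: primingkit
Title: Statistical Toolkit for Enhancer Priming and Lineage Bias in
    Multipotent Progenitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-usable implementations of the statistics used to establish
    transcription-factor-dependent enhancer priming and lineage bias in
    hematopoietic multipotent progenitors: negative-binomial differential
    testing of accessibility and pseudobulk count matrices, motif
    co-occurrence permutation z-scores against background peak subsamples,
    Tn5 cut-site footprint aggregation with randomized control envelopes,
    enhancer-anchored preranked gene-set enrichment, direction-of-transition
    (DoT) scoring on a single-cell reference landscape, and query-to-reference
    cell projection. Ships seeded synthetic-data generators that reproduce
    the statistical structure of every input, with ground-truth records for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea
Config/testthat/edition: 3
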