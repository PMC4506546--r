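Package: chipTargets
Title: Direct Transcription-Factor Target Inference from ChIP-seq and RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies direct transcription-factor target genes by integrating
    ChIP-seq binding evidence with differential gene expression. Implements a
    sliding-window peak caller with an empirical label-swap null, strand-shift
    correction and strand-balance filtering; promoter assignment with an
    exponential distance-decay binding score; a negative-binomial
    differential-expression test between genotypes; rank-product integration
    with permutation overlap tests, Kolmogorov-Smirnov comparisons of binding
    score distributions and temporal binding-expression concordance; and
    transcriptome similarity analytics (Spearman distances, classical MDS,
    complete-linkage clustering with optimal leaf ordering). A synthetic-data
    generator plants known binding and expression programs so the whole
    pipeline can be validated end to end against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
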