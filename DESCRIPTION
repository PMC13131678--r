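Package: epinorm
Title: Local-Maxima Percentile Normalization and Differential Binding
    Analysis for ChIP-Seq and CUT&RUN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Peak-centric analysis of ChIP-seq and CUT&RUN signal without
    exogenous spike-in controls. Per-base coverage tracks are built from
    aligned reads (single- or paired-end), optionally control-subtracted and
    blacklist-masked, then rescaled so that the 99th percentile of local
    signal maxima is equal across samples of a chromatin target. Candidate
    regions are derived from a grid of q-value thresholds and merge
    distances over per-condition peak sets (external ENCODE narrowPeak or
    broadPeak files, or a built-in Poisson window caller), quantified into a
    count-like matrix, and tested for differential binding with a negative
    binomial Wald test supporting RLE, TMM, upper-quartile or no
    composition scaling. Includes binned-signal PCA and correlation QC and
    a seeded synthetic-data generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    MASS,
    edgeR,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
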