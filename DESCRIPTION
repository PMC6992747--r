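Package: bivalomics
Title: Promoter Chromatin-State and RNAPII Pausing Analysis for Stimulus-Response ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Input-normalized quantification of ChIP-seq signal over
    promoter and gene-body windows, K-means clustering of promoter
    chromatin states with silhouette-based model selection, bivalent-domain
    calling from H3K4me3/H3K27me3 peak co-occurrence, differential-expression
    classification over a stimulation time course, RNA polymerase II
    pausing-index computation and pause-release summaries, and ChIP-qPCR
    chromatin-occupancy calculations. Includes a deterministic synthetic-data
    generator that emits coverage tracks, peak sets, expression and Ct tables
    with a ground-truth manifest, so every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
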