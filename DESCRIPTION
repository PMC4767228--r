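Package: epimemory
Title: Epigenetic Memory Analysis for Paired Methylome Designs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential DNA methylation analysis for paired-sample designs
    on Illumina 450k-style arrays, built around the question of epigenetic
    memory in cultured cells: per-probe moderated linear models with
    surrogate-variable adjustment, bump-hunting for differentially methylated
    regions and long-range blocks with a residual-bootstrap family-wise error
    rate, differential variability (Levene) with mean-difference filtering, a
    paired age-divergence model with trajectory clustering, methylome-wide
    Euclidean distance contrasts, methylation-expression integration,
    chromatin-state coverage enrichment, and variant-call filtering. Includes
    a synthetic-data generator with known ground truth that emulates a paired
    scalp/dura fibroblast methylome study, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    car,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
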