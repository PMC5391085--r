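Package: allelink
Title: Long-Range Allele-Specific Mapping of Regulatory Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects allelic imbalance at heterozygous SNPs in histone
    ChIP-seq and RNA-seq read counts, pairs cis-regulatory imbalance with
    allele-specific expression across chromatin interactions using phased
    genotypes and histone-mark directionality, quantifies the explanatory
    power of regulatory imbalance over genetic distance, compares
    sensitivity against an hQTL/eQTL regression arm, and trains Random
    Forest ensembles on observed pairs to rescue pairs that are untestable
    for lack of heterozygotes. Ships a synthetic panel generator with
    planted cis-regulatory effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    igraph,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
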