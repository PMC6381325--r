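Package: swarmSeq
Title: Swarm-Optimized Classification of Spliced Platelet RNA-Seq Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building RNA biomarker classifiers from blood-platelet
    RNA sequencing count data based on intron-spanning (spliced) reads.
    Implements cohort quality control (low-abundance gene filtering,
    detected-gene sample filtering, leave-one-sample-out cross-correlation),
    confounder-aware normalization combining TMM scaling against a locked
    reference sample with iterative removal of unwanted variation (RUV)
    estimated from stable control genes, negative-binomial GLM
    likelihood-ratio differential-splicing analysis, and a particle-swarm
    optimized support-vector-machine classifier with ANOVA gene ranking,
    correlation filtering, recursive feature elimination and locked
    prediction with gene-count imputation. Companion analyses cover ROC/AUC
    performance with DeLong confidence intervals, permutation and resampling
    controls, RNA-binding-protein motif scanning in untranslated regions,
    exon-skipping percent-spliced-in statistics, and correlation signatures
    around a target gene such as P-selectin.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    e1071,
    pROC,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
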