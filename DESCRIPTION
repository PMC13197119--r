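Package: tfboost
Title: In Vivo Transcription Factor Binding Prediction with Boosted Trees and Cross-TF Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cell-type-specific in vivo transcription factor (TF)
    binding at candidate cis-regulatory elements from biologically informed
    features: PWM motif scanning and total binding affinity, chromatin
    accessibility (ATAC-seq) summaries, TF footprinting, RNA expression, TF
    activity inferred by regressing enhancer probabilities on motif
    affinities, and cell-type-specific TF cooperation scores from Fisher
    exact tests. Ground-truth ChIP-seq bin labels are harmonized into
    ternary region labels. Four gradient-boosted tree model families are
    provided (general cross-TF, TF-tuned transfer, TF-only, and
    embedding-augmented) together with criss-cross tissue-by-chromosome
    ensembling, AUPR-centric evaluation under heavy class imbalance,
    ChIP-seq quality control (FRiP), and a seeded synthetic-data generator
    with planted binding structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
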