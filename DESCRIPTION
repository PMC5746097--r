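Package: PseLocWD
Title: Apoptosis Protein Subcellular Localization from Fused PseAAC and
    PsePSSM Descriptors with 2-D Wavelet Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the subcellular location of apoptosis proteins from
    primary sequence and evolutionary profiles. Per-protein descriptors fuse
    Chou's pseudo-amino-acid composition (20+lambda dimensions) with the
    pseudo position-specific scoring matrix (20+20*xi dimensions from a
    sigmoid-normalized PSSM). The dataset-level feature matrix is treated as
    a two-dimensional signal and denoised by a multilevel separable discrete
    wavelet transform with soft thresholding (universal or Birge-Massart
    threshold selection), then classified by a one-vs-one multiclass support
    vector machine. Evaluation follows the jackknife (leave-one-out) and
    self-consistency protocols with per-class sensitivity, specificity and
    Matthews correlation, overall accuracy, and one-vs-rest macro-averaged
    ROC/AUC. Includes a PSI-BLAST ASCII PSSM parser, a surrogate-profile
    generator, and a seeded synthetic-data module so the full pipeline runs
    without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    class,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
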