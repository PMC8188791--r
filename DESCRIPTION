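Package: umisat
Title: Amplification-Bias Correction for UMI-Based Single-Cell RNA-Seq via
    Unseen-Molecule Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-gene unseen molecules in UMI-based single-cell
    RNA-seq from copies-per-UMI (CU) histograms and corrects count matrices
    for pooled-amplification bias. Implements the Good-Toulmin estimator, a
    zero-truncated negative binomial (ZTNB) fit by expectation-maximization,
    and a Daley-Smith rational-function (Pade) stabilization of the
    Good-Toulmin series with histogram truncation. Supports analytic binomial
    downsampling for batch correction of datasets sequenced at unequal
    depths, pooled cross-dataset histograms with quantile normalization,
    saturation metrics (FSCM/FDCM/FMCM), Lin's concordance correlation
    coefficient, and a molecule-level simulator with negative binomial
    amplification that provides ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
biocViews: SingleCell, RNASeq, Transcriptomics, BatchEffect, Normalization
RoxygenNote: 7.3.3
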