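Package: fdrrc
Title: Fisher Discrimination Regularized Robust Coding for Tumor Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sparse-representation classification of tumor gene expression
    profiles. Learns a Fisher-discriminative structured dictionary from
    labelled training samples by alternating per-class ISTA coefficient
    updates with closed-form atom-wise dictionary updates, codes test samples
    with an iteratively reweighted robust coder that down-weights outlier
    genes through a logistic weight on squared residuals, and classifies by a
    local-center rule combining class-wise reconstruction residuals with
    coefficient-to-center distances. Includes the plain sparse representation
    classifier baseline, ReliefF gene selection, balance-division and
    stratified cross-validation evaluation protocols, and synthetic
    expression-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: Classification, GeneExpression, Microarray, DimensionReduction
RoxygenNote: 7.3.3
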