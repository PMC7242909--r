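Package: crosstalker
Title: Cluster Crosstalk Inference for Smart-seq2 Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for Smart-seq2 TPM single-cell
    expression matrices from complex tissue microenvironments. Provides
    spike-in aware quality control and renormalization, shared-nearest-neighbor
    community clustering with Wilcoxon rank-sum marker ranking, module scoring
    with covariate regression, marker-pair cell-cycle phase scoring, a
    permutation test for cluster-pair-specific ligand-receptor communication
    with heteromeric-complex handling, and L2-regularized multinomial logistic
    projection of external cells onto discovered clusters. A synthetic-data
    generator with planted cluster structure and communication signals makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    glmnet,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
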