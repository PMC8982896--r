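Package: txdiv
Title: Transcriptome Diversity Analysis for RNA-Seq Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-sample transcriptome diversity (normalized Shannon
    entropy of gene-level transcript probabilities) from RNA-seq count or TPM
    matrices and quantifies its footprint on gene expression estimates:
    gene-wise rank-based association tests with BH-FDR control, a PCA-based
    decomposition of the variance of an expression matrix explained by any
    per-sample query vector, and an accounting of how much of the variance
    captured by latent expression factors (PEER-style covariates) is
    attributable to transcriptome diversity or to other sample covariates.
    Includes TPM and trimmed-mean-of-M-values (TMM) normalization, rank
    inverse-normal transformation, an expression-based gene filter, a
    compositional count-matrix simulator with planted per-sample evenness,
    and a one-call pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
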