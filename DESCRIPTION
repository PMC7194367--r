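Package: motifBLMM
Title: Transcription Factor Motif Activity Inference with Bayesian Linear
    Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-condition transcription factor motif activities from
    an expression-by-condition matrix and a motif-score-by-gene matrix under
    a Bayesian linear mixed model whose marginal covariance is a sum of two
    Kronecker products, allowing correlated conditions and correlated noise.
    Ridge regression is recovered as the identity-covariance special case.
    Includes a matrix-normal simulation engine with block, full-positive and
    Wishart condition covariances, signal-fraction calibration by bisection,
    recovery metrics against simulated truth, k-fold cross-validation over
    genes, motif-score permutation nulls, group-difference motif ranking and
    IQR-based outlier motif selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
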