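Package: crossdecode
Title: Cross-Task Multivariate Pattern Decoding for Blocked-Design fMRI
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates blocked-design BOLD fMRI studies with known
    multivariate ground truth and analyses them with the standard
    cross-task decoding (MVPA cross-classification) pipeline:
    single-trial least-squares-all GLMs with a double-gamma
    haemodynamic response, discrete-cosine high-pass filtering and
    Gaussian spatial smoothing; per-subject linear support-vector
    decoding of two instruction conditions with stratified 10-fold
    cross-validation and label-permutation inference; transfer of the
    trained classifier onto an independent 4-alternative
    penalty-reading task with a group-level test of the
    imagery-prediction proportion against chance; and a packaged
    simulation experiment quantifying how run-blocked conditions
    combined with temporal autocorrelation inflate within-task
    cross-validated accuracy under the null while leaving
    cross-classification unbiased.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    RNifti,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
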