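Package: BregmanNMF
Title: Robust Non-Negative Matrix Factorization with Missing Values and Outliers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Entropic Bregman-proximal alternating solver for non-negative
    matrix factorization, embedded in an augmented-Lagrangian ADMM that
    simultaneously denoises a non-negative data matrix, imputes missing
    entries, and isolates sparse outliers via an l1 penalty. Includes
    holdout cross-validation for selecting the outlier-sparsity parameter,
    a synthetic-data generator for low-rank + sparse + noise + missingness
    benchmarks, CSV/TSV/MatrixMarket input and output, and a command-line
    interface. Designed for gene-expression matrices (samples by genes)
    but applicable to any non-negative data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
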