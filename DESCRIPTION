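Package: blocknmtf
Title: Block-Wise Non-Negative Matrix Tri-Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-negative matrix tri-factorization (NMTF) decomposes a
    non-negative data matrix X into three latent factors U, S and V by
    multiplicative updates that minimize the squared Frobenius
    reconstruction error, optionally under orthogonality constraints on U
    and V. The package provides the serial update rules, a block-wise
    reformulation over an N x M partition of X that is mathematically
    equivalent to the serial rules, adaptive partitioning (equal-size
    blocks for dense matrices, nonzero-balanced blocks for sparse
    matrices), a deterministic parallel execution engine whose results are
    bit-identical to single-process runs, co-cluster extraction and
    held-out rank selection, plus readers and writers for delimited dense
    matrices and MatrixMarket sparse matrices and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
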