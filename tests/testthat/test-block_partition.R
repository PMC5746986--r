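test_that("dense partitioning follows the floor formula and balances
           block dimensions", {
  g <- partition_dense(4, 4, 2, 2)
  expect_equal(g$row_bounds, c(0L, 2L, 4L))
  expect_equal(g$col_bounds, c(0L, 2L, 4L))
  g <- partition_dense(5, 3, 2, 1)
  expect_equal(g$row_bounds, c(0L, 2L, 5L))
  expect_equal(g$col_bounds, c(0L, 3L))
  g <- partition_dense(7, 5, 3, 2)
  expect_setequal(diff(g$row_bounds), c(2L, 2L, 3L))
  # spread of at most one row/column on a sweep of shapes
  for (n in c(5, 9, 16, 31)) {
    for (N in c(1, 2, 3, 5)) {
      h <- diff(partition_dense(n, 4, N, 2)$row_bounds)
      expect_lte(max(h) - min(h), 1L)
      expect_equal(sum(h), n)
    }
  }
  expect_error(partition_dense(3, 3, 4, 1), class = "nmtf_config_error")
})

test_that("sparse partitioning balances nonzeros by prefix sums", {
  # per-row nnz (6, 2, 2, 2): the first band stops right after row 1
  X <- Matrix::sparseMatrix(i = c(rep(1, 6), 2, 2, 3, 3, 4, 4),
                            j = c(1:6, 1:2, 3:4, 5:6) ,
                            x = 1, dims = c(4, 6))
  g <- partition_sparse(X, 2, 1)
  expect_equal(g$row_bounds, c(0L, 1L, 4L))
  expect_equal(g$col_bounds, c(0L, 6L))
  expect_equal(sum(g$block_nnz), 12L)

  # uniform occupancy reduces to the equal-size split
  Xu <- Matrix::sparseMatrix(i = rep(1:8, each = 4), j = rep(1:4, 8),
                             x = 1, dims = c(8, 4))
  gu <- partition_sparse(Xu, 4, 2)
  gd <- partition_dense(8, 4, 4, 2)
  expect_equal(gu$row_bounds, gd$row_bounds)
  expect_equal(gu$col_bounds, gd$col_bounds)

  # single band is the identity partition
  g1 <- partition_sparse(X, 1, 1)
  expect_equal(g1$row_bounds, c(0L, 4L))

  # all mass in the last row: the leading band would hold every row
  Xbad <- Matrix::sparseMatrix(i = rep(3, 5), j = 1:5, x = 1, dims = c(3, 5))
  expect_error(partition_sparse(Xbad, 2, 1), class = "nmtf_config_error")
})

test_that("blocks round-trip exactly for dense and sparse storage", {
  X <- rand_X(6, 4, 12)
  g <- partition_dense(6, 4, 3, 2)
  blocks <- extract_blocks(X, g)
  expect_length(blocks, 6L)
  expect_true(all(vapply(blocks, function(b) all(dim(b) == c(2, 2)),
                         logical(1))))
  expect_identical(assemble_blocks(blocks, g), X$values)

  Xs <- make_skewed_sparse(40, 25, 200, skew = 1, seed = 3)
  gs <- partition_sparse(Xs, 4, 3)
  back <- assemble_blocks(extract_blocks(Xs, gs), gs)
  expect_equal(as.matrix(back), as.matrix(Xs$values))
  # recorded per-block nnz matches a direct recount
  expect_equal(gs$block_nnz, count_block_nnz(Xs, gs))
  expect_equal(sum(gs$block_nnz), Xs$nnz)
})

test_that("nnz balancing beats the equal-rows split on skewed matrices", {
  for (seed in 1:4) {
    X <- make_skewed_sparse(120, 60, 1500, skew = 1.5, seed = seed)
    N <- 4L
    gs <- partition_sparse(X, N, 1)
    gd <- partition_dense(120, 60, N, 1)
    band_nnz <- function(g) rowSums(count_block_nnz(X, g))
    expect_lt(max(band_nnz(gs)), max(band_nnz(gd)))
  }
})
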