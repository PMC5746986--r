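# Assembled block-wise updates must reproduce the serial rules: this is
# the package's central contract.

# one assembled block-wise update of each factor on a given grid
blockwise_step <- function(X, f, g, orthogonal = FALSE, eps = 1e-12) {
  Xb <- extract_blocks(X, g)
  Ub <- blocknmtf:::split_bands(f$U, g$row_bounds)
  Vb <- blocknmtf:::split_bands(f$V, g$col_bounds)
  if (!orthogonal) {
    gram_v <- aggregate_gram(Vb)
    U2 <- do.call(rbind, lapply(seq_len(g$N), function(i)
      block_update_u(i, Xb, g, Ub[[i]], f$S, Vb, gram_v, eps)))
    gram_u <- aggregate_gram(Ub)
    V2 <- do.call(rbind, lapply(seq_len(g$M), function(j)
      block_update_v(j, Xb, g, Vb[[j]], f$S, Ub, gram_u, eps)))
    S2 <- block_update_s(f$S, block_aggregates(Xb, g, Ub, Vb), eps)
  } else {
    St <- t(f$S)
    P <- lapply(seq_len(g$N), function(i)
      Reduce(`+`, lapply(seq_len(g$M), function(j)
        blocknmtf:::kern_u_partial(Xb[[(i - 1) * g$M + j]], Vb[[j]], St))))
    A <- Reduce(`+`, lapply(seq_len(g$N), function(i)
      crossprod(Ub[[i]], P[[i]])))
    U2 <- do.call(rbind, lapply(seq_len(g$N), function(i)
      block_update_u_orth(Ub[[i]], P[[i]], A, eps)))
    Q <- lapply(seq_len(g$M), function(j)
      Reduce(`+`, lapply(seq_len(g$N), function(i)
        blocknmtf:::kern_xtu_partial(Xb[[(i - 1) * g$M + j]],
                                     Ub[[i]]))) %*% f$S)
    B <- Reduce(`+`, lapply(seq_len(g$M), function(j)
      crossprod(Vb[[j]], Q[[j]])))
    V2 <- do.call(rbind, lapply(seq_len(g$M), function(j)
      block_update_v_orth(Vb[[j]], Q[[j]], B, eps)))
    S2 <- block_update_s_orth(f$S, block_aggregates(Xb, g, Ub, Vb), eps)
  }
  list(U = U2, V = V2, S = S2)
}

test_that("band Gram sums equal the whole-factor Gram matrix", {
  f <- rand_factors(10, 6, 3, 2, 21)
  bands <- blocknmtf:::split_bands(f$U, c(0L, 4L, 10L))
  G <- aggregate_gram(bands)
  expect_equal(G, crossprod(f$U), tolerance = 1e-12)
  expect_lt(max(abs(G - t(G))), 1e-14)
  expect_gte(min(eigen(G, symmetric = TRUE)$values), -1e-12)
  expect_error(aggregate_gram(list(f$U, f$V)), class = "nmtf_error")
})

test_that("assembled single-step block updates equal the serial rules on
           every tested grid and both variants", {
  for (seed in 1:3) {
    X <- rand_X(6, 4, seed)
    f <- rand_factors(6, 4, 2, 2, seed + 10)
    serial <- list(U = update_u(X, f), V = update_v(X, f), S = update_s(X, f))
    serial_o <- list(U = update_u_orth(X, f), V = update_v_orth(X, f),
                     S = update_s_orth(X, f))
    for (gr in list(c(1, 1), c(2, 2), c(3, 2), c(2, 3))) {
      g <- partition_dense(6, 4, gr[1], gr[2])
      st <- blockwise_step(X, f, g)
      expect_lt(max(abs(st$U - serial$U)), 1e-10)
      expect_lt(max(abs(st$V - serial$V)), 1e-10)
      expect_lt(max(abs(st$S - serial$S)), 1e-10)
      so <- blockwise_step(X, f, g, orthogonal = TRUE)
      expect_lt(max(abs(so$U - serial_o$U)), 1e-10)
      expect_lt(max(abs(so$V - serial_o$V)), 1e-10)
      expect_lt(max(abs(so$S - serial_o$S)), 1e-10)
    }
  }
})

test_that("a single block degenerates to the serial rules bit for bit", {
  X <- rand_X(8, 5, 4)
  f <- rand_factors(8, 5, 3, 2, 40)
  g <- partition_dense(8, 5, 1, 1)
  st <- blockwise_step(X, f, g)
  expect_identical(st$U, update_u(X, f))
  expect_identical(st$V, update_v(X, f))
  expect_identical(st$S, update_s(X, f))
})

test_that("exact factorizations are stationary band-wise", {
  sim <- make_exact(8, 6, 2, 2, seed = 13)
  g <- partition_dense(8, 6, 2, 3)
  st <- blockwise_step(sim$X, sim$factors, g)
  expect_lt(max(abs(st$U - sim$factors$U)), 1e-10)
  expect_lt(max(abs(st$V - sim$factors$V)), 1e-10)
  expect_lt(max(abs(st$S - sim$factors$S)), 1e-10)
})

test_that("full block-wise fits track the serial fit across grids,
           variants and sparse storage", {
  X <- rand_X(60, 40, 31)
  for (variant in c("nonorthogonal", "orthogonal")) {
    cfg <- nmtf_config(5, 4, variant = variant, max_iter = 50, tol = 0,
                       check_every = 10, seed = 31)
    fs <- fit_serial(X, cfg)
    for (gr in list(c(1, 1), c(2, 2), c(3, 2), c(2, 3))) {
      g <- partition_dense(60, 40, gr[1], gr[2])
      fb <- fit_blockwise(X, cfg, g)
      expect_lt(max(abs(fb$factors$U - fs$factors$U)), 1e-8)
      expect_lt(max(abs(fb$factors$V - fs$factors$V)), 1e-8)
      expect_lt(max(abs(fb$factors$S - fs$factors$S)), 1e-8)
      expect_equal(fb$objective_trajectory, fs$objective_trajectory,
                   tolerance = 1e-8)
    }
  }
  # the 1x1 grid is bit-identical to the serial path
  cfg <- nmtf_config(5, 4, max_iter = 30, seed = 31)
  expect_identical(fit_blockwise(X, cfg)$factors, fit_serial(X, cfg)$factors)

  # sparse input follows the same contract
  Xs <- make_skewed_sparse(50, 30, 600, skew = 1, seed = 5)
  cfg <- nmtf_config(3, 3, max_iter = 40, tol = 0, seed = 5)
  fs <- fit_serial(Xs, cfg)
  fb <- fit_blockwise(Xs, cfg, partition_sparse(Xs, 2, 2))
  expect_lt(max(abs(fb$factors$U - fs$factors$U)), 1e-8)
})
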