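test_that("argmax assignment, tie-breaks and interaction ranking behave
           as documented", {
  U <- rbind(c(0, 0, 0, 1), c(0.5, 0.5, 0, 0), c(0, 2, 1, 0))
  S <- rbind(c(1, 5), c(2, 2), c(9, 1), c(0, 3))
  V <- rbind(c(1, 0), c(0.3, 0.3))
  cc <- assign_clusters(factor_triple(U, S, V))
  expect_equal(cc$row_labels, c(4L, 1L, 2L))  # ties go to the lowest index
  expect_equal(cc$col_labels, c(1L, 1L))
  expect_equal(cc$ranked_pairs$score[1], max(S))
  expect_equal(unlist(cc$ranked_pairs[1, c("row_cluster", "col_cluster")],
                      use.names = FALSE), c(3, 1))
  # descending scores with (row, col) tie-breaks
  expect_true(all(diff(cc$ranked_pairs$score) <= 0))
})

test_that("all-zero loading rows are flagged and assigned cluster 1", {
  U <- rbind(c(0, 0), c(1, 2))
  f <- factor_triple(U, diag(2), matrix(1, 3, 2))
  expect_warning(cc <- assign_clusters(f), "all-zero")
  expect_equal(cc$row_labels[1], 1L)
  expect_equal(cc$degenerate_rows, 1L)
})

test_that("labels are invariant under latent-column permutation", {
  sim <- make_cocluster(planted_model(40, 30, 3, 2, seed = 9))
  fit <- fit_cocluster(sim$X, 3, 2, seed = 9, max_iter = 50)
  f <- fit$factors
  perm <- c(3, 1, 2)
  fperm <- factor_triple(f$U[, perm], f$S[perm, ], f$V)
  a1 <- ari(assign_clusters(f)$row_labels, sim$row_labels)
  a2 <- ari(assign_clusters(fperm)$row_labels, sim$row_labels)
  expect_equal(a1, a2)
})

test_that("planted co-clusters are recovered exactly at zero noise", {
  pm <- planted_model(60, 45, 3, 2, noise_sd = 0, seed = 17)
  sim <- make_cocluster(pm)
  fit <- fit_cocluster(sim$X, 3, 2, seed = 17, max_iter = 100)
  cc <- assign_clusters(fit)
  expect_equal(ari(cc$row_labels, sim$row_labels), 1)
  expect_equal(ari(cc$col_labels, sim$col_labels), 1)
})

test_that("rank selection validates inputs and returns non-negative
           error curves", {
  sim <- make_cocluster(planted_model(30, 24, 2, 2, seed = 2))
  expect_error(select_rank(sim$X, list(c(2, 2)), holdout = 1.2),
               class = "nmtf_config_error")
  expect_error(select_rank(sim$X, list(), holdout = 0.2),
               class = "nmtf_config_error")
  sel <- select_rank(sim$X, list(c(2, 2)), holdout = 0.2,
                     cfg = nmtf_config(2, 2, seed = 2), folds = 2)
  expect_equal(sel$best, c(2, 2))
  expect_true(all(sel$curve$holdout_error >= 0))
})

test_that("held-out error prefers the planted rank pair over a
           row-merged alternative", {
  for (seed in 1:3) {
    sim <- make_cocluster(planted_model(50, 40, 3, 2, seed = seed))
    sel <- select_rank(sim$X, list(c(2, 2), c(3, 2)), holdout = 0.2,
                       cfg = nmtf_config(3, 2, seed = seed), folds = 3)
    expect_equal(sel$best, c(3, 2))
  }
})

test_that("the joint mask-weighted fit decreases its observed-entry
           objective", {
  sim <- make_cocluster(planted_model(30, 20, 2, 2, seed = 3))
  Xd <- as_dense(sim$X)
  set.seed(5)
  W <- matrix(as.numeric(runif(600) >= 0.2), 30, 20)
  for (variant in c("nonorthogonal", "orthogonal")) {
    fm <- blocknmtf:::fit_masked(Xd, W,
                                 nmtf_config(2, 2, variant = variant,
                                             max_iter = 50, tol = 0,
                                             seed = 3))
    tr <- fm$trajectory
    expect_lt(tail(tr, 1), tr[1])
    expect_gte(min(vapply(list(fm$factors$U, fm$factors$S, fm$factors$V),
                          min, numeric(1))), 0)
  }
})

test_that("cluster outputs round-trip through their text files", {
  sim <- make_cocluster(planted_model(20, 15, 2, 2, seed = 4))
  cc <- assign_clusters(fit_cocluster(sim$X, 2, 2, seed = 4, max_iter = 30))
  dir <- withr::local_tempdir()
  paths <- write_clusters(cc, dir)
  rows <- utils::read.table(paths[["rows"]], sep = "\t")
  expect_equal(rows$V2, cc$row_labels)
  pairs <- utils::read.table(paths[["pairs"]], sep = "\t", header = TRUE)
  expect_equal(nrow(pairs), 4L)
})
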