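# Fixture builders shared across test files; everything is generated in
# code under fixed seeds.

rand_factors <- function(n, m, k1, k2, seed = 1) {
  set.seed(seed)
  factor_triple(matrix(runif(n * k1, 0.2, 1), n, k1),
                matrix(runif(k1 * k2, 0.2, 1), k1, k2),
                matrix(runif(m * k2, 0.2, 1), m, k2))
}

rand_X <- function(n, m, seed = 1) {
  set.seed(seed)
  data_matrix(matrix(runif(n * m, 0, 2), n, m))
}

# objective trajectory is non-increasing up to a relative slack
expect_nonincreasing <- function(traj, rel = 1e-12) {
  drops <- diff(traj)
  allowed <- rel * pmax(head(traj, -1), 1)
  expect_true(all(drops <= allowed),
              info = sprintf("max objective increase %.3e", max(drops)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
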