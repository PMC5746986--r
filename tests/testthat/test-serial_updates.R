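scalar_f <- factor_triple(matrix(1), matrix(1), matrix(1))

test_that("scalar evaluation of every update rule matches hand computation", {
  X <- matrix(2)
  # non-orthogonal: numerator 2, denominator 1 for each rule
  expect_equal(update_u(X, scalar_f), matrix(2))
  expect_equal(update_v(X, scalar_f), matrix(2))
  expect_equal(update_s(X, scalar_f), matrix(2))
  # orthogonal U: 1 * sqrt(2 / (1*1*2)) = 1
  expect_equal(update_u_orth(X, scalar_f), matrix(1))
  expect_equal(update_v_orth(X, scalar_f), matrix(1))
  # orthogonal S shares the non-orthogonal ratio: sqrt(2)
  expect_equal(update_s_orth(X, scalar_f), matrix(sqrt(2)))
})

test_that("exact factorizations are stationary under the matching rules", {
  # non-orthogonal rules: any exact positive factorization is a fixed point
  sim <- make_exact(9, 7, 3, 2, seed = 5)
  f <- sim$factors
  rules <- list(update_u, update_v, update_s)
  olds <- list(f$U, f$V, f$S)
  for (r in seq_along(rules)) {
    new <- rules[[r]](sim$X, f)
    expect_lt(max(abs(new - olds[[r]]) / pmax(olds[[r]], 1e-300)), 1e-12)
  }
  # square-root damped rules: fixed points are the orthogonal exact
  # factorizations (U'U = I, V'V = I); the S rule is also stationary at
  # generic exact factorizations because it shares the plain S ratio
  simo <- make_exact_orthogonal(10, 8, 3, 2, seed = 5)
  fo <- simo$factors
  rules <- list(update_u_orth, update_v_orth, update_s_orth)
  olds <- list(fo$U, fo$V, fo$S)
  for (r in seq_along(rules)) {
    new <- rules[[r]](simo$X, fo)
    expect_lt(max(abs(new - olds[[r]]) / pmax(abs(olds[[r]]), 1e-12)), 1e-12)
  }
  expect_lt(max(abs(update_s_orth(sim$X, f) - f$S) / pmax(f$S, 1e-300)),
            1e-12)
})

test_that("multiplicative updates preserve zeros and non-negativity", {
  f <- rand_factors(6, 5, 3, 2, 7)
  f$U[2, 1] <- 0; f$V[3, 2] <- 0; f$S[1, 2] <- 0
  X <- rand_X(6, 5, 77)
  for (rule in list(update_u, update_u_orth)) {
    U2 <- rule(X, f)
    expect_identical(U2[2, 1], 0)
    expect_gte(min(U2), 0)
  }
  for (rule in list(update_v, update_v_orth)) {
    V2 <- rule(X, f)
    expect_identical(V2[3, 2], 0)
    expect_gte(min(V2), 0)
  }
  for (rule in list(update_s, update_s_orth)) {
    S2 <- rule(X, f)
    expect_identical(S2[1, 2], 0)
    expect_gte(min(S2), 0)
  }
})

test_that("the orthogonal S rule is the square-root damped non-orthogonal
           S step", {
  f <- rand_factors(6, 4, 2, 2, 3)
  X <- rand_X(6, 4, 33)
  ratio <- update_s(X, f) / f$S     # elementwise eq-ratio (S > 0 here)
  expect_equal(update_s_orth(X, f), f$S * sqrt(ratio), tolerance = 1e-12)
})

test_that("the non-orthogonal objective is non-increasing across seeds", {
  for (seed in 1:10) {
    X <- rand_X(30, 20, seed)
    fit <- fit_serial(X, nmtf_config(4, 3, max_iter = 100, tol = 0,
                                     check_every = 1, seed = seed))
    expect_nonincreasing(fit$objective_trajectory)
  }
})

test_that("the orthogonal variant reduces the objective from its start", {
  improved <- 0L
  for (seed in 1:20) {
    X <- rand_X(20, 15, seed + 200)
    fit <- fit_serial(X, nmtf_config(3, 2, variant = "orthogonal",
                                     max_iter = 60, tol = 0, seed = seed))
    tr <- fit$objective_trajectory
    if (tail(tr, 1) < tr[1]) improved <- improved + 1L
  }
  expect_gte(improved, 19L)
})

test_that("fitting is deterministic given the seed and stops on planted
           exact data initialized at the truth", {
  X <- rand_X(25, 18, 6)
  cfg <- nmtf_config(3, 3, max_iter = 40, seed = 6)
  f1 <- fit_serial(X, cfg)
  f2 <- fit_serial(X, cfg)
  expect_identical(f1, f2)
  expect_lte(f1$iterations_run, cfg$max_iter)

  sim <- make_exact(12, 10, 2, 2, seed = 8)
  fit <- fit_serial(sim$X, nmtf_config(2, 2, max_iter = 50, seed = 8),
                    init = sim$factors)
  expect_true(fit$converged)
  expect_lt(tail(fit$objective_trajectory, 1), 1e-16)
})
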