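## Serial (non-partitioned) multiplicative update rules.  These are the
## reference path: the block-wise engine must reproduce them to floating
## point tolerance, and with a 1x1 grid, bit for bit.  To make the 1x1
## bit-identity hold, both paths share the same computational kernels and
## the same association/grouping of every matrix product.

## ---- kernels shared with the block-wise path -----------------------------

## X %*% (V %*% S'); numerator of the U update. X may be sparse.
kern_u_partial <- function(Xv, V, St) {
  as.matrix(Xv %*% (V %*% St))
}

## X' %*% U; the raw column-side partial shared by V updates.
kern_xtu_partial <- function(Xv, U) {
  as.matrix(crossprod(Xv, U))
}

## U' %*% (X %*% V); numerator of the S update.
kern_uxv_partial <- function(Xv, U, V) {
  crossprod(U, as.matrix(Xv %*% V))
}

## Elementwise multiplicative step F <- F * num / max(F %*% D, eps).
upd_mult <- function(Fmat, num, D, eps) {
  Fmat * num / pmax(Fmat %*% D, eps)
}

## Square-root damped (orthogonal-variant) step
## F <- F * sqrt(num / max(F %*% A, eps)).
upd_orth <- function(Fmat, num, A, eps) {
  ratio <- num / pmax(Fmat %*% A, eps)
  stopifnot(all(ratio >= 0))
  Fmat * sqrt(ratio)
}

upd_s_core <- function(S, uxv, gram_u, gram_v, eps) {
  S * uxv / pmax((gram_u %*% S) %*% gram_v, eps)
}

upd_s_orth_core <- function(S, uxv, gram_u, gram_v, eps) {
  ratio <- uxv / pmax((gram_u %*% S) %*% gram_v, eps)
  stopifnot(all(ratio >= 0))
  S * sqrt(ratio)
}

## ---- public serial rules -------------------------------------------------

#' One multiplicative update of U (non-orthogonal)
#'
#' U <- U * (X V S') / (U S V'V S'), elementwise, with the denominator
#' guarded below by \code{eps}.  Zero entries of U stay zero.
#'
#' @param X data matrix.
#' @param f current \code{nmtf_factors}.
#' @param eps denominator guard.
#' @return the updated U matrix.
#' @export
update_u <- function(X, f, eps = 1e-12) {
  X <- data_matrix(X); check_shapes(X, f)
  St <- t(f$S)
  num <- kern_u_partial(X$values, f$V, St)
  D <- (f$S %*% crossprod(f$V)) %*% St
  upd_mult(f$U, num, D, eps)
}

#' One multiplicative update of V (non-orthogonal)
#'
#' V <- V * (X'U S) / (V S'U'U S), elementwise and guarded.
#'
#' @inheritParams update_u
#' @return the updated V matrix.
#' @export
update_v <- function(X, f, eps = 1e-12) {
  X <- data_matrix(X); check_shapes(X, f)
  num <- kern_xtu_partial(X$values, f$U) %*% f$S
  D <- (t(f$S) %*% crossprod(f$U)) %*% f$S
  upd_mult(f$V, num, D, eps)
}

#' One multiplicative update of S (non-orthogonal)
#'
#' S <- S * (U'X V) / (U'U S V'V), elementwise and guarded.
#'
#' @inheritParams update_u
#' @return the updated S matrix.
#' @export
update_s <- function(X, f, eps = 1e-12) {
  X <- data_matrix(X); check_shapes(X, f)
  uxv <- kern_uxv_partial(X$values, f$U, f$V)
  upd_s_core(f$S, uxv, crossprod(f$U), crossprod(f$V), eps)
}

#' One orthogonal-variant update of U
#'
#' U <- U * sqrt((X V S') / (U U'X V S')), the square-root damped rule
#' targeting U'U = I.
#'
#' @inheritParams update_u
#' @return the updated U matrix.
#' @export
update_u_orth <- function(X, f, eps = 1e-12) {
  X <- data_matrix(X); check_shapes(X, f)
  P <- kern_u_partial(X$values, f$V, t(f$S))
  A <- crossprod(f$U, P)
  upd_orth(f$U, P, A, eps)
}

#' One orthogonal-variant update of V
#'
#' V <- V * sqrt((X'U S) / (V V'X'U S)), targeting V'V = I.
#'
#' @inheritParams update_u
#' @return the updated V matrix.
#' @export
update_v_orth <- function(X, f, eps = 1e-12) {
  X <- data_matrix(X); check_shapes(X, f)
  Q <- kern_xtu_partial(X$values, f$U) %*% f$S
  B <- crossprod(f$V, Q)
  upd_orth(f$V, Q, B, eps)
}

#' One orthogonal-variant update of S
#'
#' S <- S * sqrt((U'X V) / (U'U S V'V)); shares its ratio with the
#' non-orthogonal S rule, applied as a square-root damped step.
#'
#' @inheritParams update_u
#' @return the updated S matrix.
#' @export
update_s_orth <- function(X, f, eps = 1e-12) {
  X <- data_matrix(X); check_shapes(X, f)
  uxv <- kern_uxv_partial(X$values, f$U, f$V)
  upd_s_orth_core(f$S, uxv, crossprod(f$U), crossprod(f$V), eps)
}

## ---- convergence bookkeeping shared by all fit drivers -------------------

## Runs the iteration loop: step_fun(iter) must advance the factors in
## place (environment closure) and obj_fun() must return the current
## objective.  Records the objective at iteration 0 and every
## cfg$check_every iterations; stops early on relative change < tol.
run_fit_loop <- function(cfg, step_fun, obj_fun) {
  f0 <- obj_fun()
  if (!is.finite(f0)) stop_numeric("objective is not finite at initialization")
  trajectory <- f0
  prev <- f0
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iter)) {
    step_fun(it)
    iters <- it
    if (it %% cfg$check_every == 0L || it == cfg$max_iter) {
      cur <- obj_fun()
      if (!is.finite(cur))
        stop_numeric("objective became non-finite at iteration ", it)
      trajectory <- c(trajectory, cur)
      rel <- abs(cur - prev) / max(prev, cfg$epsilon)
      prev <- cur
      if (rel < cfg$tol) { converged <- TRUE; break }
    }
  }
  list(trajectory = trajectory, converged = converged, iterations = iters)
}

new_fit_result <- function(factors, loop, grid, cfg) {
  structure(list(factors = factors,
                 objective_trajectory = loop$trajectory,
                 converged = loop$converged,
                 iterations_run = loop$iterations,
                 grid = grid, config = cfg),
            class = "nmtf_fit")
}

#' @method print nmtf_fit
#' @export
print.nmtf_fit <- function(x, ...) {
  cat(sprintf(paste0("<nmtf_fit> %s variant, ranks (%d, %d), ",
                     "%d iterations, converged: %s\n",
                     "  final objective: %.6g\n"),
              x$config$variant, x$config$k1, x$config$k2,
              x$iterations_run, x$converged,
              tail(x$objective_trajectory, 1)))
  invisible(x)
}

#' @importFrom utils tail
NULL

#' Fit NMTF with the serial (non-partitioned) update rules
#'
#' Applies the U, V, S updates in that order once per iteration, each rule
#' consuming the freshest factors.  The objective is recorded at
#' initialization and every \code{check_every} iterations; the fit stops
#' at \code{max_iter} or when the relative objective change between checks
#' drops below \code{tol}.
#'
#' @param X data matrix (dense or sparse).
#' @param cfg an \code{nmtf_config}.
#' @param init optional \code{nmtf_factors} to start from instead of the
#'   seeded random initialization.
#' @return an \code{nmtf_fit} with fields \code{factors},
#'   \code{objective_trajectory}, \code{converged}, \code{iterations_run}
#'   and \code{grid} (here the trivial 1x1 grid).
#' @examples
#' sim <- make_exact(12, 8, 2, 2, seed = 3)
#' fit <- fit_serial(sim$X, nmtf_config(2, 2, max_iter = 50, seed = 3))
#' tail(fit$objective_trajectory, 1)
#' @export
fit_serial <- function(X, cfg, init = NULL) {
  X <- data_matrix(X)
  check_config(cfg, X)
  cfg$init_scale <- resolve_init_scale(cfg, X)
  f <- if (is.null(init)) init_factors(X$n, X$m, cfg) else init
  check_shapes(X, f)
  eps <- cfg$epsilon
  orth <- cfg$variant == "orthogonal"
  step <- function(it) {
    if (orth) {
      f$U <<- update_u_orth(X, f, eps)
      f$V <<- update_v_orth(X, f, eps)
      f$S <<- update_s_orth(X, f, eps)
    } else {
      f$U <<- update_u(X, f, eps)
      f$V <<- update_v(X, f, eps)
      f$S <<- update_s(X, f, eps)
    }
  }
  loop <- run_fit_loop(cfg, step, function() reconstruction_error(X, f))
  new_fit_result(f, loop, partition_dense(X$n, X$m, 1L, 1L), cfg)
}
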