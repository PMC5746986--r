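## Block-wise multiplicative update rules.  X is partitioned into an
## N x M grid, U into N row bands U^(i), V into M bands V^(j) (by the
## columns of X); S is never partitioned.  Each rule consumes block-local
## partial products plus small k-dimensional aggregates, and its assembled
## output equals the serial rule on the whole matrices -- block partial
## sums simply regroup the rows/columns of the serial products.
##
## All sums over blocks run in ascending block index so floating-point
## results are reproducible, and the per-band arithmetic reuses the serial
## kernels so a 1x1 grid reproduces the serial path bit for bit.

block_index <- function(i, j, M) (i - 1L) * M + j

#' Sum per-band Gram matrices of a partitioned factor
#'
#' Returns \code{sum_b t(F_b) F_b}, which equals the Gram matrix of the
#' whole factor; this k x k aggregate is what workers exchange in place of
#' full factor bands.
#'
#' @param bands list of row bands of a factor matrix.
#' @return the k x k Gram matrix.
#' @export
aggregate_gram <- function(bands) {
  k <- unique(vapply(bands, ncol, integer(1)))
  if (length(k) != 1L)
    stop_validation("factor bands have inconsistent rank")
  Reduce(`+`, lapply(bands, crossprod))
}

## Per-block partial products for one grid row / the whole grid.
u_partials_row <- function(Xblocks, grid, i, Vbands, St) {
  lapply(seq_len(grid$M), function(j) {
    kern_u_partial(Xblocks[[block_index(i, j, grid$M)]], Vbands[[j]], St)
  })
}

xtu_partials_col <- function(Xblocks, grid, j, Ubands) {
  lapply(seq_len(grid$N), function(i) {
    kern_xtu_partial(Xblocks[[block_index(i, j, grid$M)]], Ubands[[i]])
  })
}

#' Block-wise update of one row band of U (non-orthogonal)
#'
#' Computes band i of the serial U rule from the blocks of grid row i:
#' numerator \code{sum_j X^(i,j) V^(j) S'}, denominator
#' \code{U^(i) (S gram_v S')} with \code{gram_v = sum_j t(V^(j)) V^(j)}.
#'
#' @param i row-band index (1-based).
#' @param Xblocks row-major list of all grid blocks of X.
#' @param grid the \code{nmtf_grid}.
#' @param Ui current band U^(i).
#' @param S current S.
#' @param Vbands list of all V bands.
#' @param gram_v precomputed k2 x k2 aggregate \code{aggregate_gram(Vbands)}.
#' @param eps denominator guard.
#' @return the updated band U^(i).
#' @export
block_update_u <- function(i, Xblocks, grid, Ui, S, Vbands, gram_v,
                           eps = 1e-12) {
  St <- t(S)
  num <- Reduce(`+`, u_partials_row(Xblocks, grid, i, Vbands, St))
  D <- (S %*% gram_v) %*% St
  upd_mult(Ui, num, D, eps)
}

#' Block-wise update of one band of V (non-orthogonal)
#'
#' Numerator \code{(sum_i t(X^(i,j)) U^(i)) S}, denominator
#' \code{V^(j) (S' gram_u S)}.
#'
#' @param j column-band index (1-based).
#' @param Vj current band V^(j).
#' @param Ubands list of all U bands.
#' @param gram_u precomputed k1 x k1 aggregate \code{aggregate_gram(Ubands)}.
#' @inheritParams block_update_u
#' @return the updated band V^(j).
#' @export
block_update_v <- function(j, Xblocks, grid, Vj, S, Ubands, gram_u,
                           eps = 1e-12) {
  num <- Reduce(`+`, xtu_partials_col(Xblocks, grid, j, Ubands)) %*% S
  D <- (t(S) %*% gram_u) %*% S
  upd_mult(Vj, num, D, eps)
}

#' Block-wise aggregates feeding the S update
#'
#' @inheritParams block_update_u
#' @param Vbands list of all V bands.
#' @return list with \code{gram_u}, \code{gram_v} and
#'   \code{uxv = sum_(i,j) t(U^(i)) X^(i,j) V^(j)} (ascending block index).
#' @export
block_aggregates <- function(Xblocks, grid, Ubands, Vbands) {
  uxv <- NULL
  for (i in seq_len(grid$N)) {
    for (j in seq_len(grid$M)) {
      p <- kern_uxv_partial(Xblocks[[block_index(i, j, grid$M)]],
                            Ubands[[i]], Vbands[[j]])
      uxv <- if (is.null(uxv)) p else uxv + p
    }
  }
  list(gram_u = aggregate_gram(Ubands), gram_v = aggregate_gram(Vbands),
       uxv = uxv)
}

#' Block-wise update of S (non-orthogonal)
#'
#' \code{S <- S * uxv / (gram_u S gram_v)}, guarded; equals the serial S
#' rule because each aggregate equals its whole-matrix counterpart.
#'
#' @param S current S.
#' @param agg aggregates from \code{\link{block_aggregates}}.
#' @param eps denominator guard.
#' @return the updated S.
#' @export
block_update_s <- function(S, agg, eps = 1e-12) {
  upd_s_core(S, agg$uxv, agg$gram_u, agg$gram_v, eps)
}

#' Block-wise orthogonal updates
#'
#' Orthogonal-variant counterparts of the block rules.  For U, band i
#' consumes its local numerator \code{P^(i) = sum_j X^(i,j) V^(j) S'} and
#' the global k1 x k1 aggregate \code{A = sum_i t(U^(i)) P^(i)}:
#' \code{U^(i) <- U^(i) * sqrt(P^(i) / (U^(i) A))}.  V is symmetric with
#' \code{Q^(j) = (sum_i t(X^(i,j)) U^(i)) S} and
#' \code{B = sum_j t(V^(j)) Q^(j)}; S shares the non-orthogonal aggregates
#' under a square root.  Assembled results equal the serial orthogonal
#' rules.
#'
#' @param Ui,Vj the band being updated.
#' @param Pi,Qj the band-local numerator.
#' @param A,B the global k x k damping aggregate.
#' @param eps denominator guard.
#' @return the updated band.
#' @name block_orth
NULL

#' @rdname block_orth
#' @export
block_update_u_orth <- function(Ui, Pi, A, eps = 1e-12) {
  upd_orth(Ui, Pi, A, eps)
}

#' @rdname block_orth
#' @export
block_update_v_orth <- function(Vj, Qj, B, eps = 1e-12) {
  upd_orth(Vj, Qj, B, eps)
}

#' @rdname block_orth
#' @param S current S.
#' @param agg aggregates from \code{\link{block_aggregates}}.
#' @export
block_update_s_orth <- function(S, agg, eps = 1e-12) {
  upd_s_orth_core(S, agg$uxv, agg$gram_u, agg$gram_v, eps)
}

## ---- shared iteration engine ---------------------------------------------
##
## One full iteration (U, then V, then S, freshest values) over the block
## state.  The only distributed work is the per-block partial products;
## `map_blocks(kern_name, args)` evaluates kern(X_block_b, args[[b]]...)
## for every block b and returns the partials in block order.  Reductions
## and band updates always run on the coordinating process in ascending
## index, which is what makes single-process and parallel execution
## bit-identical.

engine_iteration <- function(state, map_blocks) {
  grid <- state$grid; cfg <- state$cfg; eps <- cfg$epsilon
  N <- grid$N; M <- grid$M
  orth <- cfg$variant == "orthogonal"

  ## --- U update ---
  St <- t(state$S)
  partials <- map_blocks("kern_u_partial",
                         lapply(seq_len(N * M), function(b) {
                           j <- (b - 1L) %% M + 1L
                           list(state$Vb[[j]], St)
                         }))
  P <- lapply(seq_len(N), function(i) {
    Reduce(`+`, partials[block_index(i, seq_len(M), M)])
  })
  if (orth) {
    A <- Reduce(`+`, lapply(seq_len(N), function(i) {
      crossprod(state$Ub[[i]], P[[i]])
    }))
    for (i in seq_len(N)) state$Ub[[i]] <- upd_orth(state$Ub[[i]], P[[i]], A, eps)
  } else {
    gram_v <- aggregate_gram(state$Vb)
    D <- (state$S %*% gram_v) %*% St
    for (i in seq_len(N)) state$Ub[[i]] <- upd_mult(state$Ub[[i]], P[[i]], D, eps)
  }

  ## --- V update (fresh U) ---
  partials <- map_blocks("kern_xtu_partial",
                         lapply(seq_len(N * M), function(b) {
                           i <- (b - 1L) %/% M + 1L
                           list(state$Ub[[i]])
                         }))
  Q <- lapply(seq_len(M), function(j) {
    Reduce(`+`, partials[block_index(seq_len(N), j, M)]) %*% state$S
  })
  if (orth) {
    B <- Reduce(`+`, lapply(seq_len(M), function(j) {
      crossprod(state$Vb[[j]], Q[[j]])
    }))
    for (j in seq_len(M)) state$Vb[[j]] <- upd_orth(state$Vb[[j]], Q[[j]], B, eps)
  } else {
    gram_u <- aggregate_gram(state$Ub)
    D <- (St %*% gram_u) %*% state$S
    for (j in seq_len(M)) state$Vb[[j]] <- upd_mult(state$Vb[[j]], Q[[j]], D, eps)
  }

  ## --- S update (fresh U and V) ---
  partials <- map_blocks("kern_uxv_partial",
                         lapply(seq_len(N * M), function(b) {
                           i <- (b - 1L) %/% M + 1L
                           j <- (b - 1L) %% M + 1L
                           list(state$Ub[[i]], state$Vb[[j]])
                         }))
  uxv <- Reduce(`+`, partials)
  gram_u <- aggregate_gram(state$Ub)
  gram_v <- aggregate_gram(state$Vb)
  state$S <- if (orth) upd_s_orth_core(state$S, uxv, gram_u, gram_v, eps)
             else upd_s_core(state$S, uxv, gram_u, gram_v, eps)
  state
}

engine_setup_state <- function(X, cfg, grid, init = NULL) {
  X <- data_matrix(X)
  check_config(cfg, X)
  if (grid$row_bounds[grid$N + 1L] != X$n ||
      grid$col_bounds[grid$M + 1L] != X$m)
    stop_config("grid does not match matrix dimensions")
  cfg$init_scale <- resolve_init_scale(cfg, X)
  f <- if (is.null(init)) init_factors(X$n, X$m, cfg) else init
  check_shapes(X, f)
  env <- new.env(parent = emptyenv())
  env$X <- X
  env$grid <- grid
  env$cfg <- cfg
  env$Ub <- split_bands(f$U, grid$row_bounds)
  env$Vb <- split_bands(f$V, grid$col_bounds)
  env$S <- f$S
  env
}

engine_factors <- function(state) {
  factor_triple(do.call(rbind, state$Ub), state$S, do.call(rbind, state$Vb))
}

engine_run <- function(X, cfg, grid, map_blocks_factory, init = NULL) {
  state <- engine_setup_state(X, cfg, grid, init)
  map_blocks <- map_blocks_factory(state)
  step <- function(it) {
    st <- engine_iteration(state, map_blocks)
    state$Ub <- st$Ub; state$Vb <- st$Vb; state$S <- st$S
  }
  loop <- run_fit_loop(cfg, step,
                       function() reconstruction_error(state$X, engine_factors(state)))
  new_fit_result(engine_factors(state), loop, grid, cfg)
}

#' Fit NMTF with block-wise updates in a single process
#'
#' Runs full iterations of the block-wise rules (same U, V, S order as
#' \code{\link{fit_serial}}) over the given grid.  For any grid the result
#' agrees with \code{fit_serial} to floating-point tolerance; for a 1x1
#' grid the two are bit-identical.
#'
#' @param X data matrix.
#' @param cfg an \code{nmtf_config}.
#' @param grid an \code{nmtf_grid}; defaults to the trivial 1x1 grid.
#' @param init optional \code{nmtf_factors} starting point.
#' @return an \code{nmtf_fit}.
#' @examples
#' sim <- make_exact(12, 8, 2, 2, seed = 3)
#' g <- partition_dense(12, 8, 2, 2)
#' fit <- fit_blockwise(sim$X, nmtf_config(2, 2, max_iter = 30, seed = 3), g)
#' @export
fit_blockwise <- function(X, cfg, grid = NULL, init = NULL) {
  X <- data_matrix(X)
  if (is.null(grid)) grid <- partition_dense(X$n, X$m, 1L, 1L)
  engine_run(X, cfg, grid, init = init, map_blocks_factory = function(state) {
    Xblocks <- extract_blocks(state$X, state$grid)
    function(kern_name, args) {
      kern <- get(kern_name, mode = "function")
      lapply(seq_along(Xblocks), function(b) {
        do.call(kern, c(list(Xblocks[[b]]), args[[b]]))
      })
    }
  })
}
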