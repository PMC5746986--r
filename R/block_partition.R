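## Partitioning of X into an N x M grid of contiguous blocks.  Bounds are
## stored 0-based with half-open intervals [bounds[i], bounds[i+1]), which
## keeps the round-trip arithmetic unambiguous; block (i, j) of X in R
## indexing is rows (rb[i]+1):rb[i+1], columns (cb[j]+1):cb[j+1].
## U inherits the row partition; V (m x k2) is partitioned by X's columns.

new_block_grid <- function(row_bounds, col_bounds, block_nnz = NULL) {
  row_bounds <- as.integer(row_bounds); col_bounds <- as.integer(col_bounds)
  if (any(diff(row_bounds) <= 0L) || any(diff(col_bounds) <= 0L))
    stop_config("block bounds must be strictly increasing (no empty blocks)")
  structure(list(row_bounds = row_bounds, col_bounds = col_bounds,
                 N = length(row_bounds) - 1L, M = length(col_bounds) - 1L,
                 block_nnz = block_nnz),
            class = "nmtf_grid")
}

#' @method print nmtf_grid
#' @export
print.nmtf_grid <- function(x, ...) {
  cat(sprintf("<nmtf_grid> %d x %d blocks\n  row_bounds: %s\n  col_bounds: %s\n",
              x$N, x$M, paste(x$row_bounds, collapse = " "),
              paste(x$col_bounds, collapse = " ")))
  invisible(x)
}

#' Partition a dense matrix into equal-size contiguous blocks
#'
#' Row bound i is \code{floor(i * n / N)} (columns analogously), so any two
#' block heights differ by at most one row and any two block widths by at
#' most one column.
#'
#' @param n,m matrix dimensions.
#' @param N,M number of row and column blocks.
#' @return an \code{nmtf_grid} with 0-based half-open bounds.
#' @examples
#' partition_dense(5, 3, 2, 1)$row_bounds  # 0 2 5
#' @export
partition_dense <- function(n, m, N, M) {
  n <- as.integer(n); m <- as.integer(m)
  N <- as.integer(N); M <- as.integer(M)
  if (N < 1L || N > n) stop_config("need 1 <= N <= n")
  if (M < 1L || M > m) stop_config("need 1 <= M <= m")
  new_block_grid(floor((0:N) * n / N), floor((0:M) * m / M))
}

## Smallest 0-based exclusive end index at which the cumulative nnz
## reaches each target t_k = k * nnz/K, forced strictly increasing.
prefix_bounds <- function(marg_nnz, K, what) {
  L <- length(marg_nnz)
  if (K > L) stop_config("more ", what, " bands than ", what, "s")
  if (K == 1L) return(c(0L, L))
  cs <- cumsum(marg_nnz)
  total <- cs[L]
  if (total <= 0) stop_config("cannot nnz-balance a matrix with no nonzeros")
  targets <- (1:(K - 1L)) * total / K
  # first index (1-based) with cs >= target, i.e. the 0-based exclusive end
  bounds <- vapply(targets, function(t) {
    which(cs >= t - 1e-9)[1L]
  }, integer(1))
  bounds <- c(0L, bounds, L)
  # enforce strict increase; a huge row can swallow several targets
  for (k in 2:(K + 1L)) {
    if (bounds[k] <= bounds[k - 1L]) bounds[k] <- bounds[k - 1L] + 1L
  }
  if (bounds[K + 1L] != L || any(bounds > L))
    stop_config("fewer nonempty ", what, "s than requested bands; ",
                "reduce ", what, " band count")
  bounds
}

#' Partition a sparse matrix into nonzero-balanced blocks
#'
#' Row bounds are chosen by prefix sums of per-row nonzero counts: bound i
#' is the smallest index at which the cumulative row nnz reaches
#' \code{i * nnz / N}.  Column bounds are chosen independently from
#' per-column counts.  Rows or columns without nonzeros stay in whichever
#' band their index falls into.
#'
#' @param X a sparse data matrix (\code{nmtf_matrix} with sparse storage,
#'   or a \code{Matrix} sparse matrix).
#' @param N,M number of row and column bands.
#' @return an \code{nmtf_grid} whose \code{block_nnz} field holds the
#'   realized N x M per-block nonzero counts.
#' @export
partition_sparse <- function(X, N, M) {
  X <- data_matrix(X)
  if (X$storage != "sparse")
    stop_config("partition_sparse expects a sparse data matrix")
  N <- as.integer(N); M <- as.integer(M)
  if (N < 1L || N > X$n || M < 1L || M > X$m)
    stop_config("need 1 <= N <= n and 1 <= M <= m")
  v <- X$values
  row_nnz <- tabulate(v@i + 1L, nbins = X$n)
  col_nnz <- diff(v@p)
  g <- new_block_grid(prefix_bounds(row_nnz, N, "row"),
                      prefix_bounds(col_nnz, M, "column"))
  g$block_nnz <- count_block_nnz(X, g)
  g
}

#' Count nonzeros per block of a grid
#'
#' @param X a data matrix.
#' @param g an \code{nmtf_grid}.
#' @return an N x M integer matrix; its sum equals \code{X$nnz}.
#' @export
count_block_nnz <- function(X, g) {
  X <- data_matrix(X)
  if (X$storage == "sparse") {
    v <- X$values
    idx <- which(v@x > 0)
    ri <- v@i[idx] # 0-based rows of nonzeros
    cj <- rep.int(seq_len(X$m), diff(v@p))[idx] - 1L
  } else {
    nz <- which(X$values > 0) - 1L
    ri <- nz %% X$n
    cj <- nz %/% X$n
  }
  bi <- findInterval(ri, g$row_bounds[-1L]) + 1L
  bj <- findInterval(cj, g$col_bounds[-1L]) + 1L
  out <- matrix(0L, g$N, g$M)
  if (length(ri)) {
    tab <- table(factor(bi, levels = seq_len(g$N)),
                 factor(bj, levels = seq_len(g$M)))
    out <- matrix(as.integer(tab), g$N, g$M)
  }
  out
}

#' Extract the blocks X^(i,j) of a grid
#'
#' @param X a data matrix.
#' @param g an \code{nmtf_grid} consistent with X.
#' @return a row-major list of N*M blocks (element (i-1)*M + j is block
#'   (i, j)), each of the same storage kind as X.
#' @export
extract_blocks <- function(X, g) {
  X <- data_matrix(X)
  if (g$row_bounds[g$N + 1L] != X$n || g$col_bounds[g$M + 1L] != X$m)
    stop_validation("grid does not match matrix dimensions")
  v <- X$values
  out <- vector("list", g$N * g$M)
  for (i in seq_len(g$N)) {
    rows <- (g$row_bounds[i] + 1L):g$row_bounds[i + 1L]
    for (j in seq_len(g$M)) {
      cols <- (g$col_bounds[j] + 1L):g$col_bounds[j + 1L]
      out[[(i - 1L) * g$M + j]] <- v[rows, cols, drop = FALSE]
    }
  }
  out
}

#' Reassemble a matrix from its blocks
#'
#' Inverse of \code{\link{extract_blocks}}: row-then-column concatenation
#' reproduces the original matrix exactly.
#'
#' @param blocks row-major list of blocks as returned by
#'   \code{extract_blocks}.
#' @param g the grid the blocks were extracted with.
#' @return a matrix (dense or sparse, matching the block storage).
#' @export
assemble_blocks <- function(blocks, g) {
  rows <- lapply(seq_len(g$N), function(i) {
    do.call(cbind, blocks[(i - 1L) * g$M + seq_len(g$M)])
  })
  do.call(rbind, rows)
}

## Split a factor matrix (U by row_bounds, or V by col_bounds) into bands.
split_bands <- function(Fmat, bounds) {
  K <- length(bounds) - 1L
  lapply(seq_len(K), function(i) {
    Fmat[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE]
  })
}
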