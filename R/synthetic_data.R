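## Ground-truth generators used throughout the tests: exactly factorizable
## matrices, planted co-cluster matrices, and sparse matrices with a
## skewed nonzero distribution (the case the nnz-balancing partitioner is
## for).  All generators are deterministic given their seed.

#' Generate an exactly factorizable matrix
#'
#' Draws strictly positive factors U0 (n x k1), S0 (k1 x k2), V0 (m x k2)
#' with entries uniform on (0.5, 1.5) and returns X = U0 S0 V0' together
#' with the generating factors, so the reconstruction error of the truth
#' is zero to float tolerance and every update rule is stationary at it.
#'
#' @param n,m matrix dimensions.
#' @param k1,k2 planted ranks.
#' @param seed RNG seed.
#' @return list with \code{X} (a dense \code{nmtf_matrix}) and
#'   \code{factors} (an \code{nmtf_factors}).
#' @export
make_exact <- function(n, m, k1, k2, seed = 1L) {
  with_seed(seed, {
    U0 <- matrix(runif(n * k1, 0.5, 1.5), n, k1)
    S0 <- matrix(runif(k1 * k2, 0.5, 1.5), k1, k2)
    V0 <- matrix(runif(m * k2, 0.5, 1.5), m, k2)
    f <- factor_triple(U0, S0, V0)
    list(X = data_matrix(U0 %*% S0 %*% t(V0)), factors = f)
  })
}

#' Generate an exactly factorizable matrix with orthogonal U and V
#'
#' Like \code{\link{make_exact}}, but U and V are column-scaled indicator
#' matrices (disjoint supports, U'U = I and V'V = I).  The square-root
#' damped update rules are stationary only at such orthogonal
#' factorizations -- a non-negative matrix cannot be orthogonal and
#' strictly positive at the same time -- so this is the fixed-point
#' fixture for the orthogonal variant.
#'
#' @inheritParams make_exact
#' @return list with \code{X} and the generating \code{factors}.
#' @export
make_exact_orthogonal <- function(n, m, k1, k2, seed = 1L) {
  if (n < k1 || m < k2) stop_config("need n >= k1 and m >= k2")
  with_seed(seed, {
    gr <- sample(rep_len(seq_len(k1), n))
    gc <- sample(rep_len(seq_len(k2), m))
    U0 <- matrix(0, n, k1); U0[cbind(seq_len(n), gr)] <- 1
    U0 <- sweep(U0, 2, sqrt(colSums(U0^2)), "/")
    V0 <- matrix(0, m, k2); V0[cbind(seq_len(m), gc)] <- 1
    V0 <- sweep(V0, 2, sqrt(colSums(V0^2)), "/")
    S0 <- matrix(runif(k1 * k2, 0.5, 1.5), k1, k2)
    f <- factor_triple(U0, S0, V0)
    list(X = data_matrix(U0 %*% S0 %*% t(V0)), factors = f)
  })
}

#' Describe a planted co-cluster model
#'
#' Rows belong to one of k1 row clusters and columns to one of k2 column
#' clusters; entry (i, j) has mean \code{block_means[r_i, c_j]}.  Labels
#' are balanced (round-robin, then shuffled) so every cluster is
#' non-empty.
#'
#' @param n,m matrix dimensions.
#' @param k1,k2 number of row / column clusters.
#' @param block_means k1 x k2 non-negative mean matrix; default draws
#'   means uniform on (0.25, 2), giving well-separated blocks.
#' @param noise_sd standard deviation of the additive Gaussian noise;
#'   the default is 5% of the spread (max - min) of \code{block_means}.
#' @param density probability an entry is retained when sparsifying; 1
#'   keeps the matrix dense.
#' @param seed RNG seed (shared by mean drawing, labels, and noise).
#' @return an object of class \code{nmtf_planted} describing the model.
#' @export
planted_model <- function(n, m, k1, k2, block_means = NULL, noise_sd = NULL,
                          density = 1, seed = 1L) {
  if (n < k1 || m < k2)
    stop_config("need at least one row per row cluster and one column per ",
                "column cluster")
  if (density <= 0 || density > 1) stop_config("density must be in (0, 1]")
  with_seed(seed, {
    if (is.null(block_means))
      block_means <- matrix(runif(k1 * k2, 0.25, 2), k1, k2)
    if (any(block_means < 0)) stop_config("block_means must be non-negative")
    if (is.null(noise_sd))
      noise_sd <- 0.05 * (max(block_means) - min(block_means))
    if (noise_sd < 0) stop_config("noise_sd must be >= 0")
    row_labels <- sample(rep_len(seq_len(k1), n))
    col_labels <- sample(rep_len(seq_len(k2), m))
  })
  structure(list(n = n, m = m, k1 = k1, k2 = k2, block_means = block_means,
                 noise_sd = noise_sd, density = density, seed = as.integer(seed),
                 row_labels = row_labels, col_labels = col_labels),
            class = "nmtf_planted")
}

#' Realize a planted co-cluster matrix
#'
#' X_ij = max(block_means[r_i, c_j] + N(0, noise_sd), 0): Gaussian noise
#' truncated at zero, which preserves non-negativity without reordering
#' block means.  With \code{density < 1} each entry is independently kept
#' with that probability (dropped entries become zero and the result is
#' stored sparse).
#'
#' @param model an \code{nmtf_planted} description.
#' @return list with \code{X} (an \code{nmtf_matrix}), \code{row_labels}
#'   and \code{col_labels}.
#' @export
make_cocluster <- function(model) {
  stopifnot(inherits(model, "nmtf_planted"))
  with_seed(model$seed + 1L, {
    mu <- model$block_means[model$row_labels, model$col_labels, drop = FALSE]
    X <- mu
    if (model$noise_sd > 0)
      X <- pmax(mu + matrix(rnorm(model$n * model$m, sd = model$noise_sd),
                            model$n, model$m), 0)
    if (model$density < 1) {
      keep <- matrix(runif(model$n * model$m) < model$density,
                     model$n, model$m)
      X <- X * keep
      X <- data_matrix(as(X, "CsparseMatrix"), storage = "sparse")
    } else {
      X <- data_matrix(X)
    }
    list(X = X, row_labels = model$row_labels, col_labels = model$col_labels)
  })
}

#' Generate a sparse matrix with skewed row occupancy
#'
#' Allocates exactly \code{nnz} positive entries across rows with
#' power-law weights proportional to \code{rank^-skew} (skew = 0 gives
#' near-uniform rows); column positions within a row are uniform.  Row
#' counts come from largest-remainder rounding of the weights, so the
#' total is exact.
#'
#' @param n,m matrix dimensions.
#' @param nnz total number of nonzero entries (\code{<= n * m}).
#' @param skew power-law exponent of the per-row weights (>= 0).
#' @param seed RNG seed.
#' @return a sparse \code{nmtf_matrix} with exactly \code{nnz} nonzeros.
#' @export
make_skewed_sparse <- function(n, m, nnz, skew = 1, seed = 1L) {
  if (nnz > n * m) stop_config("nnz exceeds matrix capacity n * m")
  if (nnz < 1) stop_config("nnz must be >= 1")
  if (skew < 0) stop_config("skew must be >= 0")
  with_seed(seed, {
    w <- seq_len(n)^(-skew)
    # water-filling: rows that hit the column capacity m keep it, and the
    # excess is re-spread over the remaining rows in proportion to their
    # power-law weights, preserving the skew of the uncapped tail
    counts <- integer(n)
    left <- as.integer(nnz)
    while (left > 0L) {
      active <- counts < m
      t <- w[active] / sum(w[active]) * left
      add <- pmin(floor(t), m - counts[active])
      if (sum(add) == 0L) {
        # only fractional targets remain: largest remainder wins
        idx <- which(active)[order(t - floor(t), decreasing = TRUE)]
        take <- head(idx, left)
        counts[take] <- counts[take] + 1L
        left <- left - length(take)
      } else {
        counts[active] <- counts[active] + as.integer(add)
        left <- left - as.integer(sum(add))
      }
    }
    ii <- rep.int(seq_len(n), counts)
    jj <- unlist(lapply(seq_len(n), function(r) {
      if (counts[r] > 0) sample.int(m, counts[r]) else integer(0)
    }), use.names = FALSE)
    X <- Matrix::sparseMatrix(i = ii, j = jj,
                              x = runif(length(ii), 0.5, 1.5),
                              dims = c(n, m))
    data_matrix(X, storage = "sparse")
  })
}

#' Write a data matrix in the format matching its storage
#'
#' Dense matrices go to tab-delimited text (17 significant digits), sparse
#' matrices to MatrixMarket coordinate format; both round-trip exactly
#' through \code{\link{read_matrix}}.
#'
#' @param X an \code{nmtf_matrix}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_data_matrix <- function(X, path) {
  X <- data_matrix(X)
  if (X$storage == "sparse") {
    Matrix::writeMM(X$values, path)
  } else {
    write_dense_tsv(X$values, path)
  }
  invisible(path)
}
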