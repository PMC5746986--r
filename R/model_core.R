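#' blocknmtf: block-wise non-negative matrix tri-factorization
#'
#' Factorizes a non-negative matrix X (n x m) as X ~ U S V' with
#' U (n x k1), S (k1 x k2) and V (m x k2) all non-negative, by
#' multiplicative updates minimizing ||X - U S V'||_F^2.  The block-wise
#' formulation partitions X into an N x M grid (U row-partitioned, V
#' partitioned along the columns of X, S never partitioned) and produces
#' results identical to the non-partitioned computation, which is what
#' makes parallel execution safe.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats runif rnorm
#' @importFrom utils head
#' @importFrom Matrix crossprod tcrossprod
NULL

## ---- error helpers -------------------------------------------------------

stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nmtf_config_error", "nmtf_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nmtf_validation_error", "nmtf_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nmtf_numeric_error", "nmtf_error")))
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## ---- DataMatrix ----------------------------------------------------------

#' Construct a non-negative data matrix
#'
#' Wraps a dense base matrix or a sparse \code{Matrix::CsparseMatrix} with
#' validated non-negativity and nonzero bookkeeping.  Dense storage keeps a
#' base double matrix; sparse storage keeps a \code{dgCMatrix}.
#'
#' @param x a numeric matrix or a sparse \code{Matrix} object.
#' @param storage \code{"dense"}, \code{"sparse"}, or \code{"auto"} (keep
#'   sparse input sparse, dense input dense).
#' @return an object of class \code{nmtf_matrix} with fields \code{values},
#'   \code{n}, \code{m}, \code{storage} and \code{nnz}.
#' @examples
#' X <- data_matrix(matrix(1:6, 2, 3))
#' X$nnz
#' @export
data_matrix <- function(x, storage = c("auto", "dense", "sparse")) {
  storage <- match.arg(storage)
  if (inherits(x, "nmtf_matrix")) return(x)
  sparse_in <- is(x, "sparseMatrix")
  if (storage == "auto") storage <- if (sparse_in) "sparse" else "dense"
  if (storage == "sparse") {
    vals <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    vals <- Matrix::drop0(vals)
  } else {
    vals <- as.matrix(x)
    storage(vals) <- "double"
  }
  if (nrow(vals) < 1L || ncol(vals) < 1L)
    stop_validation("data matrix must have at least one row and one column")
  mn <- if (storage == "sparse") {
    if (length(vals@x)) min(vals@x) else 0
  } else min(vals)
  if (is.na(mn) || mn < 0)
    stop_validation("data matrix contains negative or missing values")
  nnz <- if (storage == "sparse") sum(vals@x > 0) else sum(vals > 0)
  structure(list(values = vals, n = nrow(vals), m = ncol(vals),
                 storage = storage, nnz = as.integer(nnz)),
            class = "nmtf_matrix")
}

`storage<-` <- function(x, value) { mode(x) <- value; x }

#' @export
dim.nmtf_matrix <- function(x) c(x$n, x$m)

#' @method print nmtf_matrix
#' @export
print.nmtf_matrix <- function(x, ...) {
  cat(sprintf("<nmtf_matrix> %d x %d, %s, nnz = %d (%.1f%%)\n",
              x$n, x$m, x$storage, x$nnz, 100 * x$nnz / (x$n * x$m)))
  invisible(x)
}

#' Coerce the values of a data matrix to a dense base matrix
#' @param X an \code{nmtf_matrix}, matrix, or sparse Matrix.
#' @return a base double matrix.
#' @export
as_dense <- function(X) {
  if (inherits(X, "nmtf_matrix")) X <- X$values
  as.matrix(X)
}

## Raw values (dense base matrix or dgCMatrix) for internal arithmetic.
mat_values <- function(X) {
  if (inherits(X, "nmtf_matrix")) X$values else X
}

## ---- FactorTriple --------------------------------------------------------

#' Construct a factor triple (U, S, V)
#'
#' @param U n x k1 non-negative matrix of row-space loadings.
#' @param S k1 x k2 non-negative interaction matrix.
#' @param V m x k2 non-negative matrix of column-space loadings.
#' @return an object of class \code{nmtf_factors}.
#' @export
factor_triple <- function(U, S, V) {
  U <- as.matrix(U); S <- as.matrix(S); V <- as.matrix(V)
  if (ncol(U) != nrow(S) || ncol(S) != ncol(V))
    stop_validation("inconsistent factor dimensions: need U (n x k1), ",
                    "S (k1 x k2), V (m x k2)")
  if (min(U) < 0 || min(S) < 0 || min(V) < 0)
    stop_validation("factors must be non-negative")
  structure(list(U = U, S = S, V = V), class = "nmtf_factors")
}

#' @method print nmtf_factors
#' @export
print.nmtf_factors <- function(x, ...) {
  cat(sprintf("<nmtf_factors> U %d x %d, S %d x %d, V %d x %d\n",
              nrow(x$U), ncol(x$U), nrow(x$S), ncol(x$S),
              nrow(x$V), ncol(x$V)))
  invisible(x)
}

check_shapes <- function(X, f) {
  if (X$n != nrow(f$U) || X$m != nrow(f$V))
    stop_validation(sprintf(
      "factor shapes (U %d x %d, V %d x %d) do not match data %d x %d",
      nrow(f$U), ncol(f$U), nrow(f$V), ncol(f$V), X$n, X$m))
  invisible(TRUE)
}

## ---- FitConfig -----------------------------------------------------------

#' Factorization configuration
#'
#' @param k1 rank of the row space (number of row-cluster latent vectors).
#' @param k2 rank of the column space.
#' @param variant \code{"nonorthogonal"} (plain multiplicative updates) or
#'   \code{"orthogonal"} (square-root damped updates targeting U'U = I,
#'   V'V = I).
#' @param max_iter maximum number of iterations.
#' @param tol relative objective-change threshold for convergence; the fit
#'   stops when |F_t - F_prev| / max(F_prev, epsilon) < tol between
#'   consecutive checks.
#' @param check_every iterations between objective evaluations.
#' @param seed integer seed for reproducible initialization.
#' @param epsilon small positive guard added below update denominators.
#' @param init_scale upper bound of the uniform initial factor values; the
#'   default \code{NULL} resolves to \code{sqrt(mean(X)/(k1*k2))} when the
#'   configuration is bound to a data matrix, so that the initial
#'   reconstruction U S V' is on the scale of X.
#' @return an object of class \code{nmtf_config}.
#' @export
nmtf_config <- function(k1, k2, variant = c("nonorthogonal", "orthogonal"),
                        max_iter = 100L, tol = 1e-5, check_every = 10L,
                        seed = 1L, epsilon = 1e-12, init_scale = NULL) {
  variant <- match.arg(variant)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (is.na(k1) || is.na(k2) || k1 < 1L || k2 < 1L)
    stop_config("ranks k1 and k2 must be positive integers")
  if (max_iter < 1L) stop_config("max_iter must be >= 1")
  if (tol < 0) stop_config("tol must be >= 0")
  if (check_every < 1L) stop_config("check_every must be >= 1")
  if (epsilon <= 0) stop_config("epsilon must be > 0")
  if (!is.null(init_scale) && init_scale <= 0)
    stop_config("init_scale must be > 0")
  structure(list(k1 = k1, k2 = k2, variant = variant,
                 max_iter = as.integer(max_iter), tol = tol,
                 check_every = as.integer(check_every),
                 seed = as.integer(seed), epsilon = epsilon,
                 init_scale = init_scale),
            class = "nmtf_config")
}

check_config <- function(cfg, X) {
  if (cfg$k1 > min(X$n, X$m) || cfg$k2 > min(X$n, X$m))
    stop_config(sprintf("ranks (%d, %d) exceed min(n, m) = %d",
                        cfg$k1, cfg$k2, min(X$n, X$m)))
  invisible(TRUE)
}

resolve_init_scale <- function(cfg, X) {
  if (!is.null(cfg$init_scale)) return(cfg$init_scale)
  mu <- sum(mat_values(X)) / (X$n * X$m)
  sc <- sqrt(mu / (cfg$k1 * cfg$k2))
  if (!is.finite(sc) || sc <= 0) sc <- 0.1
  sc
}

## ---- objective and initialization ---------------------------------------

#' Squared Frobenius reconstruction error
#'
#' Computes F(U, S, V) = ||X - U S V'||_F^2, the objective minimized by
#' all update rules in the package.
#'
#' @param X data matrix (an \code{nmtf_matrix} or coercible).
#' @param f an \code{nmtf_factors} triple.
#' @return a non-negative scalar; zero iff the factorization is exact.
#' @export
reconstruction_error <- function(X, f) {
  X <- data_matrix(X)
  check_shapes(X, f)
  R <- as_dense(X) - f$U %*% (f$S %*% t(f$V))
  sum(R * R)
}

#' Initialize latent factors with small positive random values
#'
#' Entries are drawn uniformly from (0, init_scale], so every entry is
#' strictly positive and no multiplicative update starts dead.
#' Deterministic given \code{cfg$seed}.
#'
#' @param n,m data matrix dimensions.
#' @param cfg an \code{nmtf_config}; \code{init_scale} must be set (bind
#'   the config to a matrix via the fitting functions to use the
#'   data-driven default).
#' @return an \code{nmtf_factors} triple.
#' @export
init_factors <- function(n, m, cfg) {
  if (cfg$k1 > min(n, m) || cfg$k2 > min(n, m))
    stop_config(sprintf("ranks (%d, %d) exceed min(n, m) = %d",
                        cfg$k1, cfg$k2, min(n, m)))
  sc <- if (is.null(cfg$init_scale)) 0.1 else cfg$init_scale
  with_seed(cfg$seed, {
    # 1 - runif() lies in (0, 1], keeping factors strictly positive
    U <- matrix((1 - runif(n * cfg$k1)) * sc, n, cfg$k1)
    S <- matrix((1 - runif(cfg$k1 * cfg$k2)) * sc, cfg$k1, cfg$k2)
    V <- matrix((1 - runif(m * cfg$k2)) * sc, m, cfg$k2)
    factor_triple(U, S, V)
  })
}
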