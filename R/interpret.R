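## Interpretation of fitted factors: hard co-cluster assignments from the
## row-wise argmax of U and V, interaction strengths from S, and rank
## selection by reconstruction error on held-out entries.

#' Extract co-cluster assignments from fitted factors
#'
#' Row i is assigned to the row cluster with the largest loading in
#' U[i, ]; column j likewise from V[j, ].  Ties break to the lowest
#' index.  Cluster interactions are read off S, and all (row cluster,
#' column cluster) pairs are ranked by interaction strength.
#'
#' @param f an \code{nmtf_factors} (or the \code{factors} of an
#'   \code{nmtf_fit}).
#' @return an object of class \code{nmtf_coclusters}: \code{row_labels}
#'   (1..k1), \code{col_labels} (1..k2), \code{interaction_scores} (S),
#'   \code{ranked_pairs} (data frame sorted by descending score, ties by
#'   row then column index), and \code{degenerate_rows} /
#'   \code{degenerate_cols} flagging all-zero loading rows, which are
#'   assigned cluster 1 with a warning.
#' @export
assign_clusters <- function(f) {
  if (inherits(f, "nmtf_fit")) f <- f$factors
  stopifnot(inherits(f, "nmtf_factors"))
  deg_r <- which(rowSums(f$U) == 0)
  deg_c <- which(rowSums(f$V) == 0)
  if (length(deg_r) || length(deg_c))
    warning("all-zero factor rows assigned to cluster 1: ",
            length(deg_r), " row(s), ", length(deg_c), " column(s)")
  row_labels <- max.col(f$U, ties.method = "first")
  col_labels <- max.col(f$V, ties.method = "first")
  k1 <- ncol(f$U); k2 <- ncol(f$V)
  pairs <- data.frame(row_cluster = rep(seq_len(k1), times = k2),
                      col_cluster = rep(seq_len(k2), each = k1),
                      score = as.vector(f$S))
  pairs <- pairs[order(-pairs$score, pairs$row_cluster, pairs$col_cluster), ]
  rownames(pairs) <- NULL
  structure(list(row_labels = row_labels, col_labels = col_labels,
                 interaction_scores = f$S, ranked_pairs = pairs,
                 degenerate_rows = deg_r, degenerate_cols = deg_c),
            class = "nmtf_coclusters")
}

#' @method print nmtf_coclusters
#' @export
print.nmtf_coclusters <- function(x, ...) {
  cat(sprintf("<nmtf_coclusters> %d row clusters, %d column clusters\n",
              nrow(x$interaction_scores), ncol(x$interaction_scores)))
  cat("top interactions:\n")
  print(head(x$ranked_pairs, 3))
  invisible(x)
}

#' Fit a factorization for co-cluster discovery
#'
#' Multiplicative updates from a random start converge to low
#' reconstruction error but, when the planted signal has rank below k1
#' (always the case for k1 > k2), the minimizer is not unique and the
#' argmax read-out of U need not align with clusters.  Following common
#' co-clustering practice, this driver seeds U and V from k-means
#' partitions of the rows and columns (membership weight 1, off-cluster
#' weight \code{jitter} so no entry is multiplicatively dead) and S from
#' the per-block means, then refines with the update rules -- by default
#' the orthogonal variant, whose implicit orthogonality pressure keeps U
#' and V near indicator matrices.
#'
#' @param X data matrix.
#' @param k1,k2 number of row and column clusters.
#' @param variant update-rule variant used for refinement.
#' @param max_iter refinement iterations.
#' @param seed seed for the k-means starts.
#' @param nstart random k-means restarts.
#' @param jitter off-cluster membership weight in (0, 1).
#' @param grid optional \code{nmtf_grid} for block-wise refinement.
#' @return an \code{nmtf_fit}.
#' @export
fit_cocluster <- function(X, k1, k2, variant = "orthogonal", max_iter = 200L,
                          seed = 1L, nstart = 5L, jitter = 0.2, grid = NULL) {
  X <- data_matrix(X)
  Xd <- as_dense(X)
  km <- with_seed(seed, list(r = stats::kmeans(Xd, k1, nstart = nstart),
                             c = stats::kmeans(t(Xd), k2, nstart = nstart)))
  U0 <- matrix(jitter, X$n, k1); U0[cbind(seq_len(X$n), km$r$cluster)] <- 1
  V0 <- matrix(jitter, X$m, k2); V0[cbind(seq_len(X$m), km$c$cluster)] <- 1
  S0 <- matrix(0, k1, k2)
  for (r in seq_len(k1)) for (cc in seq_len(k2))
    S0[r, cc] <- mean(Xd[km$r$cluster == r, km$c$cluster == cc])
  S0[!is.finite(S0)] <- mean(Xd)
  S0 <- pmax(S0, 1e-8)
  cfg <- nmtf_config(k1, k2, variant, max_iter = max_iter, tol = 0,
                     check_every = max(1L, as.integer(max_iter)), seed = seed)
  fit_blockwise(X, cfg, grid, init = factor_triple(U0, S0, V0))
}

## ---- mask-weighted fitting for held-out rank selection -------------------

## Multiplicative updates restricted to observed entries: with W the 0/1
## observation mask, every residual term X - U S V' is replaced by
## W * X and W * (U S V'), in both numerators and denominators, so masked
## entries contribute nothing to the gradient.
fit_masked <- function(Xd, W, cfg) {
  n <- nrow(Xd); m <- ncol(Xd)
  cfg$init_scale <- if (is.null(cfg$init_scale)) {
    mu <- sum(Xd * W) / max(sum(W), 1)
    sc <- sqrt(mu / (cfg$k1 * cfg$k2)); if (!is.finite(sc) || sc <= 0) 0.1 else sc
  } else cfg$init_scale
  f <- init_factors(n, m, cfg)
  eps <- cfg$epsilon
  WX <- W * Xd
  obj <- function() {
    R <- W * (Xd - f$U %*% (f$S %*% t(f$V)))
    sum(R * R)
  }
  # explicit loop: the masked denominators are full products, not Gram forms
  orth <- cfg$variant == "orthogonal"
  f0 <- obj(); trajectory <- f0; prev <- f0; converged <- FALSE; iters <- 0L
  if (!is.finite(f0)) stop_numeric("objective is not finite at initialization")
  for (it in seq_len(cfg$max_iter)) {
    St <- t(f$S)
    if (orth) {
      # masked counterparts of the square-root damped rules: X -> W * X
      Nu <- WX %*% (f$V %*% St)
      f$U <- f$U * sqrt(Nu / pmax(f$U %*% crossprod(f$U, Nu), eps))
      Nv <- crossprod(WX, f$U) %*% f$S
      f$V <- f$V * sqrt(Nv / pmax(f$V %*% crossprod(f$V, Nv), eps))
      Wh <- W * (f$U %*% (f$S %*% t(f$V)))
      f$S <- f$S * sqrt(crossprod(f$U, WX %*% f$V) /
                          pmax(crossprod(f$U, Wh %*% f$V), eps))
    } else {
      Wh <- W * (f$U %*% (f$S %*% t(f$V)))
      f$U <- f$U * (WX %*% (f$V %*% St)) / pmax(Wh %*% (f$V %*% St), eps)
      Wh <- W * (f$U %*% (f$S %*% t(f$V)))
      f$V <- f$V * (crossprod(WX, f$U) %*% f$S) /
        pmax(crossprod(Wh, f$U) %*% f$S, eps)
      Wh <- W * (f$U %*% (f$S %*% t(f$V)))
      f$S <- f$S * crossprod(f$U, WX %*% f$V) /
        pmax(crossprod(f$U, Wh %*% f$V), eps)
    }
    iters <- it
    if (it %% cfg$check_every == 0L || it == cfg$max_iter) {
      cur <- obj()
      if (!is.finite(cur)) stop_numeric("objective became non-finite")
      trajectory <- c(trajectory, cur)
      rel <- abs(cur - prev) / max(prev, eps)
      prev <- cur
      if (rel < cfg$tol) { converged <- TRUE; break }
    }
  }
  list(factors = f, trajectory = trajectory, converged = converged,
       iterations = iters)
}

## Squared error on held-out entries for one candidate under the
## membership-locked evaluation: row/column memberships come from k-means
## on the (imputed) observed matrix, U and V are the corresponding hard
## indicators, and only S is refined with the mask-weighted multiplicative
## rule.  Locking the memberships keeps the candidates comparable as
## clustering models: a jointly refined fit with k1 > k2 can always
## collapse onto a min(k1, k2)-dimensional solution of identical error,
## which makes the row rank invisible to reconstruction.
holdout_error_memberships <- function(Xd, W, k1, k2, seed, nstart,
                                      refine_iter, eps) {
  n <- nrow(Xd); m <- ncol(Xd)
  rmean <- rowSums(W * Xd) / pmax(rowSums(W), 1)
  Ximp <- Xd
  miss <- W == 0
  Ximp[miss] <- matrix(rmean, n, m)[miss]
  km <- with_seed(seed, list(r = stats::kmeans(Ximp, k1, nstart = nstart),
                             c = stats::kmeans(t(Ximp), k2, nstart = nstart)))
  U <- matrix(0, n, k1); U[cbind(seq_len(n), km$r$cluster)] <- 1
  V <- matrix(0, m, k2); V[cbind(seq_len(m), km$c$cluster)] <- 1
  S <- matrix(mean(Xd), k1, k2)
  WX <- W * Xd
  for (it in seq_len(refine_iter)) {
    Wh <- W * (U %*% (S %*% t(V)))
    S <- S * crossprod(U, WX %*% V) / pmax(crossprod(U, Wh %*% V), eps)
  }
  sum(((1 - W) * (Xd - U %*% (S %*% t(V))))^2)
}

holdout_error_joint <- function(Xd, W, cfg, restarts) {
  best <- NULL
  base_seed <- cfg$seed
  for (t in seq_len(max(restarts, 1L))) {
    cfg$seed <- as.integer((base_seed + 7919L * (t - 1L)) %% 2147483647)
    fm <- fit_masked(Xd, W, cfg)
    train <- tail(fm$trajectory, 1)
    if (is.null(best) || train < best$train)
      best <- list(train = train, factors = fm$factors)
  }
  fh <- best$factors
  sum(((1 - W) * (Xd - fh$U %*% (fh$S %*% t(fh$V))))^2)
}

#' Select factorization ranks by held-out reconstruction error
#'
#' Repeatedly masks a random fraction of entries, fits each candidate
#' rank pair on the observed entries only, and returns the candidate with
#' the smallest total squared error on the held-out entries across folds.
#'
#' Two evaluation modes are provided.  The default,
#' \code{refine = "memberships"}, treats each candidate as a co-clustering
#' model: row and column memberships are estimated by k-means on the
#' observed (row-mean-imputed) matrix, U and V are fixed at the resulting
#' indicator matrices, and S alone is refined by the mask-weighted
#' multiplicative rule.  \code{refine = "joint"} instead runs fully
#' mask-weighted multiplicative updates of U, S and V from random starts.
#' Joint refinement cannot distinguish a candidate's larger rank from any
#' candidate sharing the same \code{min(k1, k2)} -- the factorization can
#' always collapse U onto U S without changing the reconstruction -- so
#' the membership-locked mode is the one that recovers a planted rank
#' pair.
#'
#' @param X data matrix (densified internally).
#' @param candidates list of c(k1, k2) pairs.
#' @param holdout fraction of entries to hold out per fold, in (0, 1).
#' @param cfg an \code{nmtf_config} whose ranks are overridden per
#'   candidate; its seed drives masks, k-means starts and random
#'   initializations.
#' @param folds number of independent holdout masks averaged over.
#' @param refine \code{"memberships"} or \code{"joint"} (see Details).
#' @param refine_iter mask-weighted S updates per fold in membership mode.
#' @param nstart k-means restarts in membership mode.
#' @param restarts random restarts per candidate in joint mode; the
#'   restart with the lowest training error is the one scored.
#' @return list with \code{best} (the winning c(k1, k2)), \code{curve}
#'   (data frame of candidate ranks and their total held-out errors) and
#'   \code{holdout}.
#' @examples
#' sim <- make_cocluster(planted_model(40, 30, 3, 2, seed = 5))
#' sel <- select_rank(sim$X, list(c(2, 2), c(3, 2)), holdout = 0.2,
#'                    nmtf_config(3, 2, max_iter = 60, seed = 5))
#' sel$best
#' @export
select_rank <- function(X, candidates, holdout = 0.2, cfg = nmtf_config(2, 2),
                        folds = 5L, refine = c("memberships", "joint"),
                        refine_iter = 100L, nstart = 5L, restarts = 3L) {
  refine <- match.arg(refine)
  if (holdout <= 0 || holdout >= 1)
    stop_config("holdout fraction must be in (0, 1)")
  if (!length(candidates)) stop_config("no candidate ranks supplied")
  X <- data_matrix(X)
  Xd <- as_dense(X)
  errs <- numeric(length(candidates))
  for (fold in seq_len(max(folds, 1L))) {
    mask_seed <- as.integer((as.numeric(cfg$seed) * 48271 + fold) %%
                              2147483647)
    W <- with_seed(mask_seed, {
      matrix(as.numeric(runif(X$n * X$m) >= holdout), X$n, X$m)
    })
    if (sum(W) == 0 || sum(1 - W) == 0)
      stop_config("degenerate holdout mask; adjust the holdout fraction")
    errs <- errs + vapply(seq_along(candidates), function(ci) {
      k <- candidates[[ci]]
      ck <- cfg; ck$k1 <- as.integer(k[1]); ck$k2 <- as.integer(k[2])
      ck$init_scale <- NULL
      check_config(ck, X)
      if (refine == "memberships")
        holdout_error_memberships(Xd, W, ck$k1, ck$k2,
                                  seed = as.integer((cfg$seed + fold) %%
                                                      2147483647),
                                  nstart = nstart,
                                  refine_iter = refine_iter,
                                  eps = cfg$epsilon)
      else holdout_error_joint(Xd, W, ck, restarts)
    }, numeric(1))
  }
  curve <- data.frame(k1 = vapply(candidates, `[`, numeric(1), 1),
                      k2 = vapply(candidates, `[`, numeric(1), 2),
                      holdout_error = errs)
  list(best = unlist(candidates[[which.min(errs)]]), curve = curve,
       holdout = holdout)
}

#' Write co-cluster assignments and ranked interactions to text files
#'
#' Assignments go to two-column tab-delimited files (index, label);
#' ranked pairs to a tab-delimited file with header.
#'
#' @param cc an \code{nmtf_coclusters}.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_clusters <- function(cc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rows = file.path(dir, "row_clusters.tsv"),
             cols = file.path(dir, "col_clusters.tsv"),
             pairs = file.path(dir, "ranked_pairs.tsv"))
  utils::write.table(data.frame(index = seq_along(cc$row_labels),
                                label = cc$row_labels),
                     paths[["rows"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(index = seq_along(cc$col_labels),
                                label = cc$col_labels),
                     paths[["cols"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cc$ranked_pairs, paths[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  paths
}
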