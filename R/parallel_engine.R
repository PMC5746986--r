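## Parallel execution of the block-wise factorization.  One worker per
## block (p = N*M).  Each worker holds its X block for the whole run and
## computes the block-local partial products; the coordinating process
## reduces partials in ascending block index, applies the band updates,
## and broadcasts the fresh bands each stage needs.  Because reductions
## and updates happen once, in a fixed order, with the same kernels as the
## single-process engine, the factors are bit-identical for every worker
## count.

#' Build the staged execution plan for one iteration
#'
#' Describes, worker by worker, the computations and exchanges of one full
#' iteration (U, V, S updates) in the barrier-aligned stage style of a
#' 2x2-blocks-on-4-units workflow: local partials, exchange of partials
#' toward the reducer, k-dimensional aggregate broadcast, band update,
#' band broadcast where a receiving worker cannot recompute the band
#' locally.  Exchanges of whole factor bands are only planned when both
#' grid dimensions exceed one: with a single row of blocks (1xM) every
#' worker spans the full row dimension and updates U from the shared
#' aggregates itself, so no U-band payload ever moves (symmetrically, no
#' V-band payloads on Nx1 grids) -- this is why tall matrices favor
#' row-wise partitioning and wide matrices column-wise.
#'
#' @param grid an \code{nmtf_grid}.
#' @param p worker count; must equal \code{N * M} (one block per worker)
#'   or 1.
#' @param k1,k2 factorization ranks, used only to size the recorded
#'   payloads (default 1 records sizes per latent vector).
#' @return an object of class \code{nmtf_plan}: the worker assignment and
#'   an ordered list of stages, each with a name, the computing workers,
#'   and its exchanges \code{(from, to, role, elements)}.
#' @export
build_plan <- function(grid, p, k1 = 1L, k2 = 1L) {
  N <- grid$N; M <- grid$M
  p <- as.integer(p)
  if (p != N * M && p != 1L)
    stop_config(sprintf("worker count %d must equal N*M = %d or 1", p, N * M))
  rb <- diff(grid$row_bounds); cb <- diff(grid$col_bounds)
  workers <- data.frame(worker = seq_len(max(p, 1L)),
                        i = rep(seq_len(N), each = M)[seq_len(p)],
                        j = rep(seq_len(M), times = N)[seq_len(p)])
  if (p == 1L) { workers <- data.frame(worker = 1L, i = NA, j = NA) }

  stages <- list()
  add_stage <- function(name, compute, exchanges) {
    stages[[length(stages) + 1L]] <<- list(name = name, compute = compute,
                                           exchanges = exchanges)
  }
  no_xch <- data.frame(from = integer(0), to = integer(0),
                       role = character(0), elements = integer(0))
  xch <- function(from, to, role, elements) {
    if (!length(from) || !length(to)) return(no_xch)
    data.frame(from = from, to = to, role = role, elements = elements)
  }
  if (p == 1L) {
    for (nm in c("u_partials", "u_update", "v_partials", "v_update",
                 "s_partials", "s_update"))
      add_stage(nm, 1L, no_xch)
    return(structure(list(grid = grid, p = 1L, workers = workers,
                          stages = stages), class = "nmtf_plan"))
  }

  reducer <- 1L # coordinating worker performing reductions and S update
  ## one factor update: partial exchange -> aggregate broadcast -> band step
  plan_factor <- function(fac, K, owner_band, band_rows, kfac) {
    # partials: every worker computes its block partial locally
    add_stage(paste0(fac, "_partials"), workers$worker, no_xch)
    # partials move to the band reducer unless the band is local to one worker
    ex <- NULL
    leads <- vapply(seq_len(K), function(b)
      min(workers$worker[owner_band == b]), integer(1))
    for (b in seq_len(K)) {
      others <- setdiff(workers$worker[owner_band == b], leads[b])
      if (length(others))
        ex <- rbind(ex, xch(others, leads[b], paste0(fac, "_partial"),
                            band_rows[b] * kfac))
    }
    add_stage(paste0(fac, "_reduce"), leads,
              if (is.null(ex)) no_xch else ex)
    # k x k damping aggregate broadcast to every band leader
    add_stage(paste0(fac, "_aggregate"), reducer,
              xch(reducer, setdiff(leads, reducer), paste0(fac, "_gram"),
                  kfac * kfac))
    # band update by each leader; redistribute only if row-mates exist in
    # both grid dimensions (otherwise receivers recompute from aggregates)
    ex <- NULL
    if (N > 1L && M > 1L) {
      for (b in seq_len(K)) {
        others <- setdiff(workers$worker[owner_band == b], leads[b])
        if (length(others))
          ex <- rbind(ex, xch(leads[b], others, paste0(fac, "_band"),
                              band_rows[b] * kfac))
      }
    }
    add_stage(paste0(fac, "_update"), leads,
              if (is.null(ex)) no_xch else ex)
  }
  plan_factor("u", N, workers$i, rb, as.integer(k1))
  plan_factor("v", M, workers$j, cb, as.integer(k2))
  # S: uxv partials reduce to the coordinator, S broadcast to all
  add_stage("s_partials", workers$worker, no_xch)
  add_stage("s_reduce", reducer,
            xch(setdiff(workers$worker, reducer), reducer, "uxv_partial",
                as.integer(k1) * as.integer(k2)))
  add_stage("s_update", reducer,
            xch(reducer, setdiff(workers$worker, reducer), "s_full",
                as.integer(k1) * as.integer(k2)))
  structure(list(grid = grid, p = p, workers = workers, stages = stages),
            class = "nmtf_plan")
}

#' @method print nmtf_plan
#' @export
print.nmtf_plan <- function(x, ...) {
  cat(sprintf("<nmtf_plan> %d x %d grid on %d worker(s), %d stages\n",
              x$grid$N, x$grid$M, x$p, length(x$stages)))
  for (s in x$stages)
    cat(sprintf("  %-12s compute: %-12s exchanges: %d\n", s$name,
                paste(s$compute, collapse = ","), nrow(s$exchanges)))
  invisible(x)
}

## roles of payloads that are whole factor bands (for minimality checks)
plan_band_exchanges <- function(plan, role) {
  do.call(rbind, lapply(plan$stages, function(s)
    s$exchanges[s$exchanges$role == role, , drop = FALSE]))
}

## ---- cluster-backed execution --------------------------------------------

## Bootstrap closure evaluated on each worker; built in the global
## environment so its serialization does not drag the (not yet loadable)
## package namespace along.
make_bootstrap <- function() {
  f <- function(lp) { .libPaths(lp); loadNamespace("blocknmtf"); TRUE }
  environment(f) <- globalenv()
  f
}

#' Run block-wise NMTF on p parallel workers
#'
#' Starts a PSOCK cluster of \code{p} workers (one grid block each),
#' executes the staged plan of \code{\link{build_plan}}, and returns a fit
#' whose factors are bit-identical to \code{\link{fit_blockwise}} on the
#' same grid, seed and configuration: block partials are computed on the
#' owning workers, while reductions (ascending block index) and band
#' updates happen once on the coordinator.
#'
#' @param X data matrix.
#' @param cfg an \code{nmtf_config}.
#' @param grid an \code{nmtf_grid}.
#' @param p worker count (\code{N * M}, or 1 for the single-process path).
#' @param init optional \code{nmtf_factors} starting point.
#' @return an \code{nmtf_fit}; its \code{plan} field records the stage
#'   plan used.
#' @export
run_parallel <- function(X, cfg, grid, p, init = NULL) {
  X <- data_matrix(X)
  plan <- build_plan(grid, p, cfg$k1, cfg$k2)
  if (p == 1L) {
    fit <- fit_blockwise(X, cfg, grid, init = init)
    fit$plan <- plan
    return(fit)
  }
  cl <- parallel::makePSOCKcluster(p)
  on.exit(parallel::stopCluster(cl), add = TRUE)
  parallel::clusterApply(cl, rep(list(.libPaths()), p), make_bootstrap())
  fit <- engine_run(X, cfg, grid, init = init, map_blocks_factory = function(state) {
    Xblocks <- extract_blocks(state$X, state$grid)
    # each worker pins its block once; iterations ship only factor bands
    parallel::clusterApply(cl, Xblocks, function(b) {
      assign(".nmtf_block", b, envir = globalenv()); TRUE
    })
    function(kern_name, args) {
      parallel::clusterApply(cl, args, function(a, kn) {
        kern <- getFromNamespace(kn, "blocknmtf")
        do.call(kern, c(list(get(".nmtf_block", envir = globalenv())), a))
      }, kn = kern_name)
    }
  })
  fit$plan <- plan
  fit
}

#' @importFrom utils getFromNamespace
NULL
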