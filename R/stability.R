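#' Canonical form of a partition
#'
#' Community ids are relabelled 1..m in order of each community's smallest
#' member index, so two partitions are equal iff their canonical forms are
#' identical and comparisons are label-invariant.
#'
#' @param p integer (or factor/character) community assignment, one entry per
#'   node; names, if present, are preserved.
#' @return integer vector with contiguous ids starting at 1.
#' @export
canonical_partition <- function(p) {
  out <- match(p, unique(p))
  names(out) <- names(p)
  out
}

#' Number of communities of a partition
#' @param p a partition vector.
#' @return integer.
#' @export
n_communities <- function(p) length(unique(p))

# indicator matrix H of a partition (n x m)
indicator_matrix <- function(p) {
  p <- canonical_partition(p)
  m <- max(p)
  H <- matrix(0, length(p), m)
  H[cbind(seq_along(p), p)] <- 1
  H
}

#' Normalised variation of information between two partitions
#'
#' The information-theoretic distance
#' `VI = (2 H(P, P') - H(P) - H(P')) / log n`, with Shannon entropies of the
#' community relative frequencies (natural log; the normalisation by `log n`
#' makes the base irrelevant and bounds the value in `[0, 1]`). VI is a metric
#' on canonical partitions.
#'
#' @param p,q partitions over the same node set (same length; if both are
#'   named, names must agree).
#' @param normalise divide by `log n` (default `TRUE`).
#' @return numeric in `[0, 1]` (unnormalised value if `normalise = FALSE`).
#' @export
variation_of_information <- function(p, q, normalise = TRUE) {
  if (length(p) != length(q))
    stop("partitions are defined over different node sets")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    if (!setequal(names(p), names(q)))
      stop("partitions are defined over different node sets")
    q <- q[names(p)]
  }
  .vi_cpp(as.integer(canonical_partition(p)), as.integer(canonical_partition(q)),
          normalise)
}

#' Mean pairwise variation of information of an ensemble
#'
#' The average normalised VI over all ordered pairs of distinct ensemble
#' members, `1/(l(l-1)) * sum_{i != j} VI(P_i, P_j)`; low values signal that
#' the optimisation lands on the same partition from random initialisations.
#'
#' @param ensemble list of partitions over the same node set.
#' @return numeric in `[0, 1]`; 0 with a warning when fewer than 2 members.
#' @export
ensemble_vi <- function(ensemble) {
  if (length(ensemble) < 2L) {
    warning("ensemble has fewer than 2 members; <VI> defined as 0")
    return(0)
  }
  .ensemble_vi_cpp(lapply(ensemble, function(p)
    as.integer(canonical_partition(p))))
}

#' Normalised conditional entropy between partitions
#'
#' Entry `(i, j)` is `H(P_j | P_i) / log n`: the residual uncertainty about
#' the assignment under `P_j` once `P_i` is known. The entry is zero exactly
#' when `P_j` is a coarsening of `P_i`, so for a strictly hierarchical
#' sequence of partitions the matrix is zero above the diagonal; nonzero
#' upper-triangular entries pinpoint non-hierarchical merges.
#'
#' @param partitions list of partitions over the same node set.
#' @return square matrix of normalised conditional entropies.
#' @export
conditional_entropy_matrix <- function(partitions) {
  k <- length(partitions)
  n <- length(partitions[[1]])
  H <- function(p) { f <- tabulate(p) / n; -sum(f[f > 0] * log(f[f > 0])) }
  joint <- function(p, q) {
    f <- as.numeric(table(p, q)) / n
    -sum(f[f > 0] * log(f[f > 0]))
  }
  out <- matrix(0, k, k)
  ps <- lapply(partitions, canonical_partition)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) out[i, j] <- (joint(ps[[i]], ps[[j]]) - H(ps[[i]])) / log(n)
  }
  pmax(out, 0)
}

# B(t) = Pi exp(t(M - I)) - pi^T pi, the (node-level) autocovariance matrix
# of the diffusion; `kernel` lets sweeps reuse a precomputed exp(t(M-I)).
autocovariance_matrix <- function(ts, t, kernel = NULL) {
  K <- kernel %||% heat_kernels(ts, t)[[1]]
  ts$pi * K - tcrossprod(ts$pi)
}

#' Clustered autocovariance matrix
#'
#' `R(t, H) = H^T (Pi exp(t(M - I)) - pi^T pi) H`: entry `(c, f)` is the
#' probability that a walker starting in community `c` under the stationary
#' distribution is found in community `f` after Markov time `t`, minus the
#' probability of that event at stationarity.
#'
#' @param ts a `transition_system`.
#' @param p a partition of the nodes.
#' @param t Markov time (non-negative).
#' @return m x m matrix.
#' @export
clustered_autocovariance <- function(ts, p, t) {
  stopifnot(t >= 0)
  H <- indicator_matrix(p)
  crossprod(H, autocovariance_matrix(ts, t) %*% H)
}

#' Markov Stability of a partition
#'
#' The trace of the clustered autocovariance: the total probability of flow
#' remaining trapped within communities over Markov time `t`, in excess of
#' chance. The all-in-one partition has stability 0 at every time; the
#' singleton partition at `t = 0` has stability `1 - sum(pi^2)`.
#'
#' @inheritParams clustered_autocovariance
#' @return numeric stability value.
#' @export
stability <- function(ts, p, t) {
  sum(diag(clustered_autocovariance(ts, p, t)))
}

# stability of an assignment against a precomputed B matrix
stability_from_B <- function(B, p) {
  p <- canonical_partition(p)
  sum(B[outer(p, p, "==")])
}

#' Optimise Markov Stability at one time
#'
#' Runs a Louvain-style greedy optimisation of the stability objective `ell`
#' times from seeded random initial visit orders and returns the ensemble
#' together with the best member. The objective `trace H^T B(t) H` is
#' invariant under symmetrisation of `B`, so the optimiser works on
#' `(B + B^T)/2`, the standard reduction that makes modularity-type
#' heuristics applicable to directed flows.
#'
#' @param ts a `transition_system`.
#' @param t Markov time.
#' @param ell ensemble size (number of optimisation runs).
#' @param seed integer seed; run `k` uses a seed derived from `(seed, k)`.
#' @param kernel optional precomputed heat kernel at `t`.
#' @return list with `best` (partition), `r` (its stability), `ensemble`
#'   (list of partitions), `r_values`.
#' @export
optimise_partition <- function(ts, t, ell = 100, seed = 1, kernel = NULL) {
  stopifnot(ell >= 1)
  B <- autocovariance_matrix(ts, t, kernel)
  Bs <- (B + t(B)) / 2
  runs <- lapply(seq_len(ell), function(k) {
    .louvain_cpp(Bs, as.integer(derive_seed(seed, k) %% 2147483647))
  })
  rvals <- vapply(runs, function(r) r$quality, 0)
  best <- which.max(rvals)
  ensemble <- lapply(runs, function(r)
    stats::setNames(canonical_partition(r$assignment), ts$nodes))
  list(best = ensemble[[best]], r = rvals[best],
       ensemble = ensemble, r_values = rvals)
}

#' Sweep Markov Stability across Markov times
#'
#' For each time on the grid, optimises the stability objective with an
#' `ell`-member ensemble, records the best partition, its stability, and the
#' ensemble robustness `<VI>(t)`; finally assembles the cross-time matrix
#' `VI(t, t')` between best partitions. Scanning the Markov time acts as a
#' resolution parameter: partitions coarsen as `t` grows.
#'
#' @param ts a `transition_system`.
#' @param times increasing positive Markov-time grid (default 200 log-spaced
#'   points on `[0.01, 1000]`).
#' @param ell ensemble size per time (the reference analysis uses 100;
#'   screens use less).
#' @param seed master seed; per-time seeds are derived deterministically.
#' @return an object of class `markov_sweep`: list with `times`, `partitions`
#'   (n x T matrix), `n_communities`, `r`, `mean_vi`, `cross_vi`, `ell`,
#'   `seed`, `nodes`.
#' @export
markov_sweep <- function(ts, times = geomspace(0.01, 1000, 200), ell = 100,
                         seed = 1) {
  stopifnot(all(times > 0), !is.unsorted(times, strictly = TRUE))
  kernels <- heat_kernels(ts, times)
  nt <- length(times)
  n <- length(ts$nodes)
  parts <- matrix(NA_integer_, n, nt, dimnames = list(ts$nodes, NULL))
  r <- numeric(nt)
  mvi <- numeric(nt)
  for (k in seq_len(nt)) {
    opt <- optimise_partition(ts, times[k], ell = ell,
                              seed = derive_seed(seed, k), kernel = kernels[[k]])
    parts[, k] <- opt$best
    r[k] <- opt$r
    mvi[k] <- if (ell >= 2) .ensemble_vi_cpp(lapply(opt$ensemble, as.integer)) else 0
  }
  cross <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) if (j > i)
    cross[i, j] <- cross[j, i] <- .vi_cpp(parts[, i], parts[, j], TRUE)
  structure(list(times = times, partitions = parts,
                 n_communities = apply(parts, 2, function(p) length(unique(p))),
                 r = r, mean_vi = mvi, cross_vi = cross, ell = ell,
                 seed = seed, nodes = ts$nodes),
            class = "markov_sweep")
}

#' @exportS3Method base::print
print.markov_sweep <- function(x, ...) {
  cat(sprintf("<markov_sweep> %d nodes, %d times in [%g, %g], ell = %d\n",
              length(x$nodes), length(x$times), min(x$times), max(x$times),
              x$ell))
  cat(sprintf("  communities: %d (t = %g) down to %d (t = %g)\n",
              x$n_communities[1], x$times[1],
              x$n_communities[length(x$times)], max(x$times)))
  invisible(x)
}

#' Select robust partitions from a sweep
#'
#' A partition is reported when it is both persistent -- optimal over a
#' maximal contiguous run of Markov times on which the best partition stays
#' VI-identical (pairwise VI below `eps_plateau`) with a constant community
#' count -- and consistent -- the ensemble robustness `<VI>(t)` dips below
#' `dip_threshold` somewhere in the run. Within each qualifying run the
#' partition at the time of lowest `<VI>(t)` is returned.
#'
#' @param sweep a `markov_sweep`.
#' @param eps_plateau VI threshold under which two best partitions count as
#'   identical (default 0.02).
#' @param dip_threshold `<VI>` threshold for consistency (default 0.05).
#' @param min_len minimal number of grid points for a plateau (default 2).
#' @param truncate_washout drop times after the optimal community count jumps
#'   sharply upwards (default `TRUE`). On the optimal curve the community
#'   count shrinks as Markov time grows; once the autocovariance has decayed
#'   to numerical noise the optimiser degenerates back towards singletons,
#'   and plateaux found there are artefacts.
#' @return list of selections, each with `partition`, `t_start`, `t_end`,
#'   `t_best`, `mean_vi`, `n_communities`.
#' @export
select_robust_partitions <- function(sweep, eps_plateau = 0.02,
                                     dip_threshold = 0.05, min_len = 2L,
                                     truncate_washout = TRUE) {
  nt <- length(sweep$times)
  if (nt < 2L) return(list())
  if (truncate_washout && nt > 2L) {
    m <- sweep$n_communities
    jump <- which(m[-1] > 2 * m[-nt] & m[-1] > 4)
    if (length(jump)) {
      sweep$times <- sweep$times[seq_len(jump[1])]
      sweep$partitions <- sweep$partitions[, seq_len(jump[1]), drop = FALSE]
      sweep$n_communities <- m[seq_len(jump[1])]
      sweep$mean_vi <- sweep$mean_vi[seq_len(jump[1])]
      sweep$cross_vi <- sweep$cross_vi[seq_len(jump[1]), seq_len(jump[1]),
                                       drop = FALSE]
      nt <- jump[1]
      if (nt < 2L) return(list())
    }
  }
  same <- vapply(seq_len(nt - 1), function(k) {
    sweep$n_communities[k] == sweep$n_communities[k + 1] &&
      sweep$cross_vi[k, k + 1] < eps_plateau
  }, TRUE)
  runs <- list()
  start <- 1L
  for (k in seq_len(nt - 1)) {
    if (!same[k]) {
      runs[[length(runs) + 1L]] <- c(start, k)
      start <- k + 1L
    }
  }
  runs[[length(runs) + 1L]] <- c(start, nt)
  out <- list()
  for (rg in runs) {
    len <- rg[2] - rg[1] + 1L
    if (len < min_len) next
    idx <- rg[1]:rg[2]
    if (min(sweep$mean_vi[idx]) >= dip_threshold) next
    best <- idx[which.min(sweep$mean_vi[idx])]
    out[[length(out) + 1L]] <- list(
      partition = stats::setNames(sweep$partitions[, best], sweep$nodes),
      t_start = sweep$times[rg[1]], t_end = sweep$times[rg[2]],
      t_best = sweep$times[best], mean_vi = sweep$mean_vi[best],
      n_communities = sweep$n_communities[best])
  }
  out
}

#' Exhaustive Markov Stability optimum
#'
#' Enumerates all set partitions (feasible for about 12 nodes or fewer) and
#' returns the one maximising stability at time `t`. Intended as a ground
#' truth to validate the heuristic optimiser on small graphs.
#'
#' @param ts a `transition_system` over a small node set.
#' @param t Markov time.
#' @return list with `best` partition and its stability `r`.
#' @export
exhaustive_best_partition <- function(ts, t) {
  n <- length(ts$nodes)
  if (n > 12) stop("exhaustive enumeration is limited to n <= 12")
  B <- autocovariance_matrix(ts, t)
  Bs <- (B + t(B)) / 2
  best_r <- -Inf
  best_p <- NULL
  # restricted-growth-string enumeration of set partitions
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      r <- stability_from_B(Bs, rgs)
      if (r > best_r) {
        best_r <<- r
        best_p <<- rgs
      }
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, 0L)
  list(best = stats::setNames(canonical_partition(best_p), ts$nodes),
       r = best_r)
}
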