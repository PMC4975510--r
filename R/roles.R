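#' Role-based-similarity feature matrix
#'
#' Each node gets a feature vector counting its damped in- and out-paths of
#' increasing lengths: column blocks are the row sums of `(beta A^T)^k`
#' (incoming paths) and `(beta A)^k` (outgoing paths) for `k = 1..K`, with
#' `beta = alpha / lambda1` and `lambda1` the spectral radius of `A`, so that
#' contributions decay geometrically with path length. When `K` is not given
#' it grows until appending a block changes no node's normalised feature
#' direction by more than `tol` (capped at `k_max`).
#'
#' @param x a `connectome`.
#' @param alpha damping parameter in (0, 1); 0.95 by default.
#' @param K number of path-length scales, or `NULL` for the stopping rule.
#' @param tol direction-change tolerance for the stopping rule.
#' @param k_max cap on `K`.
#' @return an object of class `feature_matrix`: list with `X` (n x 2K),
#'   `K`, `alpha`, `beta`, `lambda1`, `nodes`.
#' @export
feature_matrix <- function(x, alpha = 0.95, K = NULL, tol = 1e-8,
                           k_max = 50L) {
  stopifnot(alpha > 0, alpha < 1)
  A <- x$A
  n <- nrow(A)
  if (n == 0 || sum(A) == 0) stop("empty graph")
  lambda1 <- max(Mod(eigen(A, only.values = TRUE)$values))
  # nilpotent adjacency (acyclic graph): paths die out after at most n steps
  beta <- if (lambda1 > 1e-12) alpha / lambda1 else alpha
  kcap <- if (is.null(K)) min(k_max, if (lambda1 > 1e-12) k_max else n) else K
  ones <- rep(1, n)
  vin <- ones
  vout <- ones
  cols_in <- list()
  cols_out <- list()
  prev_dir <- NULL
  for (k in seq_len(kcap)) {
    vin <- beta * as.numeric(crossprod(A, vin))   # (beta A^T)^k row sums
    vout <- beta * as.numeric(A %*% vout)         # (beta A)^k row sums
    cols_in[[k]] <- vin
    cols_out[[k]] <- vout
    if (is.null(K)) {
      Xk <- cbind(do.call(cbind, cols_in), do.call(cbind, cols_out))
      nrm <- sqrt(rowSums(Xk^2))
      dir <- Xk / ifelse(nrm > 0, nrm, 1)
      if (!is.null(prev_dir)) {
        # previous directions padded with the two new zero columns
        pad <- cbind(prev_dir[, seq_len(k - 1), drop = FALSE], 0,
                     prev_dir[, (k - 1) + seq_len(k - 1), drop = FALSE], 0)
        if (max(abs(dir - pad)) < tol) break
      }
      prev_dir <- dir
    }
  }
  X <- cbind(do.call(cbind, cols_in), do.call(cbind, cols_out))
  rownames(X) <- x$nodes
  colnames(X) <- c(paste0("in_", seq_along(cols_in)),
                   paste0("out_", seq_along(cols_out)))
  structure(list(X = X, K = length(cols_in), alpha = alpha, beta = beta,
                 lambda1 = lambda1, nodes = x$nodes),
            class = "feature_matrix")
}

#' Cosine similarity of flow profiles
#'
#' `Y_ij = x_i . x_j / (|x_i| |x_j|)` over the rows of the feature matrix.
#' Values lie in `[0, 1]` because features are non-negative. Nodes with an
#' all-zero feature vector (isolated with respect to damped paths) get a zero
#' similarity row by convention, with a warning.
#'
#' @param fm a `feature_matrix` (or a plain non-negative matrix).
#' @return n x n similarity matrix `Y`.
#' @export
similarity_matrix <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sum(zero), " node(s) with all-zero feature vectors; ",
            "their similarity is set to 0")
  Xn <- X / ifelse(nrm > 0, nrm, 1)
  Y <- tcrossprod(Xn)
  Y[zero, ] <- 0
  Y[, zero] <- 0
  Y <- pmin(pmax(Y, 0), 1)
  diag(Y)[!zero] <- 1
  Y
}

#' Relaxed minimum spanning tree of a similarity matrix
#'
#' Converts similarity to distance `d = 1 - Y`, builds the minimum spanning
#' tree, and additionally retains every edge `(i, j)` whose distance beats
#' the weakest link on the MST path between `i` and `j` relaxed by a local
#' density offset: `d_ij < maxlink_ij + gamma (d_i^k + d_j^k)`, where
#' `d_i^k` is the distance from `i` to its `k`-th nearest neighbour. The
#' result always contains the MST and is therefore connected.
#'
#' @param Y symmetric similarity matrix with entries in `[0, 1]`.
#' @param k neighbour index for the local density term (default 1).
#' @param gamma relaxation strength (default 0.5).
#' @return an `igraph` undirected graph; edge attribute `weight` carries the
#'   similarity `Y`, `distance` the distance `1 - Y`, and the logical
#'   attribute `mst` marks tree edges.
#' @export
rmst_graph <- function(Y, k = 1L, gamma = 0.5) {
  n <- nrow(Y)
  D <- 1 - Y
  diag(D) <- 0
  # zero distances (identical profiles) get an epsilon so the graph keeps
  # those edges; they are always retained below
  Dg <- D
  Dg[Dg <= 0] <- 1e-12
  diag(Dg) <- 0
  g_full <- igraph::graph_from_adjacency_matrix(Dg, mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g_full, weights = igraph::E(g_full)$weight)
  # max-link distance along the unique MST path between every pair, by
  # traversal from each root over the tree
  adj <- igraph::as_adj_list(mst)
  wmat <- matrix(0, n, n)
  mst_ends <- igraph::ends(mst, igraph::E(mst), names = FALSE)
  mst_w <- igraph::E(mst)$weight
  wadj <- matrix(0, n, n)
  wadj[mst_ends] <- mst_w
  wadj[mst_ends[, c(2, 1), drop = FALSE]] <- mst_w
  for (root in seq_len(n)) {
    maxlink <- rep(0, n)
    visited <- rep(FALSE, n)
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in as.integer(adj[[v]])) {
        if (!visited[u]) {
          visited[u] <- TRUE
          maxlink[u] <- max(maxlink[v], wadj[v, u])
          queue <- c(queue, u)
        }
      }
    }
    wmat[root, ] <- maxlink
  }
  dk <- apply(D + diag(Inf, n), 1, function(r) sort(r)[k])
  keep <- D < wmat + gamma * outer(dk, dk, "+")
  keep[D <= 0] <- TRUE
  diag(keep) <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  keep[mst_ends] <- TRUE
  keep <- keep | t(keep)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$distance <- D[idx]
  igraph::E(g)$weight <- Y[idx]
  igraph::E(g)$mst <- wadj[idx] > 0 | D[idx] == 0
  igraph::V(g)$name <- rownames(Y) %||% as.character(seq_len(n))
  g
}

#' Cluster a similarity graph into flow roles
#'
#' Runs the Markov Stability sweep on the (undirected, weighted) similarity
#' graph and picks, among the robust partitions selected by the plateau/dip
#' criteria, the one with the lowest ensemble `<VI>` and at least two
#' communities; if nothing qualifies, the best partition at the time of
#' minimal `<VI>(t)` is used. Role ids are ordered by descending mean
#' out-strength of their members in the original connectome, so role 1 is
#' the most source-like.
#'
#' @param sim_graph an `igraph` graph from [rmst_graph()] (edge `weight` =
#'   similarity).
#' @param x the original `connectome` (for role ordering).
#' @param tau,times,ell,seed passed to the stability machinery.
#' @param ... passed to [select_robust_partitions()].
#' @return an object of class `role_assignment`: list with `labels` (named
#'   integer vector), `n_roles`, `sweep`, `selection`.
#' @export
cluster_roles <- function(sim_graph, x, tau = 0.85,
                          times = geomspace(0.01, 1000, 50), ell = 20,
                          seed = 1, ...) {
  W <- as.matrix(igraph::as_adjacency_matrix(sim_graph, attr = "weight",
                                             sparse = TRUE))
  dimnames(W) <- list(igraph::V(sim_graph)$name, igraph::V(sim_graph)$name)
  sim_conn <- new_connectome(chem = matrix(0, nrow(W), ncol(W),
                                           dimnames = dimnames(W)),
                             gap = W)
  ts <- build_transition_system(sim_conn, tau)
  sw <- markov_sweep(ts, times = times, ell = ell, seed = seed)
  sel <- select_robust_partitions(sw, ...)
  n <- length(sw$nodes)
  # Teleportation bounds the structural signal by exp(-(1 - tau) t): the
  # second eigenvalue of M is at most tau, so the autocovariance decays to
  # numerical noise beyond this horizon and plateaux starting there are
  # optimisation artefacts, not flow structure.
  t_wash <- log(1e3) / (1 - tau)
  # candidate role partitions: robust, coarse-grained (micro-scale plateaus
  # with more than n/2 communities are resolution noise for role purposes)
  # and rooted before the washout horizon
  cand <- Filter(function(s)
    s$n_communities >= 2 && s$n_communities <= n / 2 &&
      s$t_start <= t_wash, sel)
  if (length(cand)) {
    mv <- vapply(cand, `[[`, 0, "mean_vi")
    span <- vapply(cand, function(s)
      log(min(s$t_end, t_wash)) - log(s$t_start), 0)
    tb <- vapply(cand, `[[`, 0, "t_best")
    # most consistent plateau; ties resolved by the longest-lived plateau
    # within the horizon, then by the earlier Markov time
    best <- which(mv <= min(mv) + 1e-12)
    best <- best[span[best] >= max(span[best]) - 1e-12]
    pick <- cand[[best[which.min(tb[best])]]]
    labels <- pick$partition
  } else if (length(sel)) {
    # no mid-scale robust structure: take the coarsest robust plateau (for a
    # graph of interchangeable nodes this is the single all-in-one role),
    # breaking ties by plateau length
    ms <- vapply(sel, `[[`, 0, "n_communities")
    span <- vapply(sel, function(s) log(s$t_end) - log(s$t_start), 0)
    cand2 <- which(ms == min(ms))
    pick <- sel[[cand2[which.max(span[cand2])]]]
    labels <- pick$partition
  } else {
    labels <- stats::setNames(rep(1L, n), sw$nodes)
    pick <- NULL
  }
  # nodes with (numerically) identical flow profiles are interchangeable and
  # must share a role, even where the stability optimum leaves them apart
  # (for duplicate profiles the trace objective strictly prefers singletons)
  wts <- igraph::E(sim_graph)$weight
  dup <- igraph::subgraph_from_edges(sim_graph,
                                     igraph::E(sim_graph)[wts >= 1 - 1e-9],
                                     delete.vertices = FALSE)
  comp <- igraph::components(dup)$membership[names(labels)]
  for (cmp in unique(comp)) {
    memb <- names(labels)[comp == cmp]
    if (length(memb) > 1) labels[memb] <- labels[memb[1]]
  }
  labels <- stats::setNames(canonical_partition(labels), names(labels))
  # order roles by mean out-strength (descending): sources first
  d <- out_strengths(x)[names(labels)]
  means <- tapply(d, labels, mean)
  remap <- match(labels, as.integer(names(sort(means, decreasing = TRUE))))
  labels <- stats::setNames(as.integer(remap), names(labels))
  structure(list(labels = labels, n_roles = length(unique(labels)),
                 sweep = sw, selection = pick),
            class = "role_assignment")
}

#' Extract flow roles from a connectome
#'
#' End-to-end role-based-similarity pipeline: feature matrix, cosine
#' similarity, relaxed-minimum-spanning-tree sparsification, and stability
#' clustering of the similarity graph.
#'
#' @param x a `connectome`.
#' @param alpha damping parameter for [feature_matrix()].
#' @param k,gamma RMST parameters.
#' @param ... passed to [cluster_roles()].
#' @return a `role_assignment`; the similarity matrix is attached as
#'   attribute `Y` and the similarity graph as attribute `graph`.
#' @export
flow_roles <- function(x, alpha = 0.95, k = 1L, gamma = 0.5, ...) {
  fm <- feature_matrix(x, alpha = alpha)
  Y <- similarity_matrix(fm)
  g <- rmst_graph(Y, k = k, gamma = gamma)
  roles <- cluster_roles(g, x, ...)
  attr(roles, "Y") <- Y
  attr(roles, "graph") <- g
  roles
}

#' Summarise flow roles
#'
#' Per-role membership counts, S/I/M percentages, mean in-/out-strengths and
#' PageRank quartiles, plus the role-to-role aggregated stationary flow
#' matrix `F_rs = sum_{i in r, j in s} pi_i M_ij` (row sums equal the total
#' stationary flow of each role's members) and, when soma positions are
#' available, a kernel-smoothed soma-position density per role.
#'
#' @param roles a `role_assignment`.
#' @param x the `connectome`.
#' @param ts the matching `transition_system`.
#' @return list with `table` (data frame), `flow` (matrix), `soma_density`
#'   (list of `stats::density` objects or NULL).
#' @export
role_summary <- function(roles, x, ts) {
  labels <- roles$labels[x$nodes]
  rs <- sort(unique(labels))
  din <- in_strengths(x)
  dout <- out_strengths(x)
  pr <- ts$pi
  tab <- do.call(rbind, lapply(rs, function(r) {
    i <- labels == r
    ty <- factor(x$node_type[i], levels = c("S", "I", "M", "unknown"))
    q <- stats::quantile(pr[i], c(0.25, 0.5, 0.75))
    data.frame(role = r, n = sum(i),
               pct_S = 100 * mean(ty == "S"), pct_I = 100 * mean(ty == "I"),
               pct_M = 100 * mean(ty == "M"),
               mean_in_strength = mean(din[i]),
               mean_out_strength = mean(dout[i]),
               pagerank_q25 = q[1], pagerank_q50 = q[2], pagerank_q75 = q[3],
               row.names = NULL)
  }))
  H <- indicator_matrix(labels)
  flow <- crossprod(H, (ts$pi * ts$M) %*% H)
  dimnames(flow) <- list(paste0("R", rs), paste0("R", rs))
  dens <- NULL
  if (any(!is.na(x$soma_position))) {
    dens <- lapply(rs, function(r) {
      s <- x$soma_position[labels == r & !is.na(x$soma_position)]
      if (length(s) >= 2) stats::density(s, from = 0, to = 1) else NULL
    })
    names(dens) <- paste0("R", rs)
  }
  list(table = tab, flow = flow, soma_density = dens)
}
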