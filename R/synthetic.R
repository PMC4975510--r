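#' Specify a synthetic connectome
#'
#' Defines a seeded generator for directed, weighted, integer-valued networks
#' that emulate the statistical structure of a real connectome: a two-level
#' assortative block hierarchy (fine blocks nested in coarse blocks), a mix
#' of symmetric gap-junction-like and asymmetric chemical-synapse-like edges,
#' planted upstream/downstream flow roles biasing edge direction, at least
#' one pure sink, and optional bridge nodes wired across several fine blocks
#' as known disruptive targets for ablation screens.
#'
#' The defaults echo the headline statistics of the *C. elegans* somatic
#' connectome: 279 nodes, mean out-strength about 29 synapses, mean edge
#' weight about 2.7 (geometric law on positive integers), and a symmetric
#' share of edge weight of about 887/6394.
#'
#' @param n_nodes number of nodes.
#' @param fine_per_coarse integer vector: number of fine blocks inside each
#'   coarse block (length = number of coarse blocks).
#' @param p_in_fine,p_in_coarse,p_out directed edge probabilities for node
#'   pairs in the same fine block, same coarse block (different fine), and
#'   different coarse blocks; must satisfy
#'   `p_in_fine >= p_in_coarse >= p_out` (assortative planting).
#' @param weight_mean mean of the geometric synapse-count law on {1, 2, ...}.
#' @param frac_symmetric fraction of within-fine-block edges duplicated in
#'   reverse with equal weight (gap-junction channel), in `[0, 1]`.
#' @param role_plan character vector over fine blocks with values
#'   `"upstream"`, `"middle"` or `"downstream"` (ordered layers); `NULL`
#'   assigns the first coarse block upstream and the rest downstream.
#' @param role_bias probability in `[0, 1]` that a cross-role edge respects
#'   the downstream direction of the layer ordering; at 1 no edge points
#'   against it (e.g. downstream -> upstream).
#' @param n_sinks number of nodes forced to zero out-strength
#'   (`< n_nodes`).
#' @param n_bridges number of bridge nodes whose out-edges are rewired
#'   uniformly across at least 3 foreign fine blocks.
#' @param bridge_frac fraction of a bridge node's out-edges rewired
#'   (default 1: the whole out-neighbourhood spans foreign blocks, making
#'   the bridge a genuinely disruptive deletion target).
#' @param seed RNG seed; identical spec + seed give identical output.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 279, fine_per_coarse = c(3, 3),
                           p_in_fine = 0.15, p_in_coarse = 0.03,
                           p_out = 0.005, weight_mean = 2.7,
                           frac_symmetric = 887 / 6394, role_plan = NULL,
                           role_bias = 1, n_sinks = 1, n_bridges = 1,
                           bridge_frac = 1, seed = 1) {
  spec <- list(n_nodes = n_nodes, fine_per_coarse = fine_per_coarse,
               p_in_fine = p_in_fine, p_in_coarse = p_in_coarse,
               p_out = p_out, weight_mean = weight_mean,
               frac_symmetric = frac_symmetric, role_plan = role_plan,
               role_bias = role_bias, n_sinks = n_sinks,
               n_bridges = n_bridges, bridge_frac = bridge_frac, seed = seed)
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  chk <- function(cond, field, msg)
    if (!cond) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  chk(is.numeric(spec$n_nodes) && spec$n_nodes >= 2, "n_nodes",
      "must be an integer >= 2")
  chk(all(spec$fine_per_coarse >= 1), "fine_per_coarse",
      "each coarse block needs at least one fine block")
  for (f in c("p_in_fine", "p_in_coarse", "p_out"))
    chk(spec[[f]] >= 0 && spec[[f]] <= 1, f, "must be a probability in [0, 1]")
  chk(spec$p_in_fine >= spec$p_in_coarse && spec$p_in_coarse >= spec$p_out,
      "p_in_fine", "requires p_in_fine >= p_in_coarse >= p_out")
  chk(spec$weight_mean >= 1, "weight_mean", "must be >= 1")
  chk(spec$frac_symmetric >= 0 && spec$frac_symmetric <= 1, "frac_symmetric",
      "must lie in [0, 1]")
  chk(spec$role_bias >= 0 && spec$role_bias <= 1, "role_bias",
      "must lie in [0, 1]")
  chk(spec$n_sinks >= 0 && spec$n_sinks < spec$n_nodes, "n_sinks",
      "must satisfy 0 <= n_sinks < n_nodes")
  nf <- sum(spec$fine_per_coarse)
  chk(spec$n_nodes >= nf, "n_nodes", "need at least one node per fine block")
  if (!is.null(spec$role_plan)) {
    chk(length(spec$role_plan) == nf, "role_plan",
        "must name one role per fine block")
    chk(all(spec$role_plan %in% c("upstream", "middle", "downstream")),
        "role_plan", "values must be 'upstream', 'middle' or 'downstream'")
  }
  invisible(spec)
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Realises a [synthetic_spec()]: draws directed block-model edges with
#' geometric integer weights, duplicates a fraction of within-block edges in
#' reverse as the symmetric gap-junction channel, biases cross-role edges in
#' the upstream -> downstream direction, forces the requested sinks to zero
#' out-strength, rewires bridge nodes across at least 3 foreign fine blocks,
#' and attaches S/I/M type labels (correlated with the planted roles) and
#' soma positions (correlated with fine blocks).
#'
#' @param spec a `synthetic_spec`.
#' @return list with `connectome` (a [new_connectome()]) and `truth`, a list
#'   with `fine_partition`, `coarse_partition`, `role_labels`,
#'   `bridge_nodes`, `sink_nodes`.
#' @export
generate_connectome <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, generate_connectome_impl(spec))
}

# sample from a vector without the base-R scalar surprise
resample <- function(x, size, replace = FALSE)
  x[sample.int(length(x), size, replace = replace)]

generate_connectome_impl <- function(spec) {
  n <- spec$n_nodes
  nf <- sum(spec$fine_per_coarse)
  nodes <- sprintf("N%03d", seq_len(n))

  # contiguous near-equal fine blocks, nested in coarse blocks
  fine <- sort(rep_len(seq_len(nf), n))
  coarse_of_fine <- rep(seq_along(spec$fine_per_coarse), spec$fine_per_coarse)
  coarse <- coarse_of_fine[fine]
  role_plan <- spec$role_plan %||%
    ifelse(coarse_of_fine == 1L, "upstream", "downstream")
  role <- role_plan[fine]

  # directed edge probabilities by block relation, thinned against role bias
  P <- matrix(spec$p_out, n, n)
  same_coarse <- outer(coarse, coarse, "==")
  same_fine <- outer(fine, fine, "==")
  P[same_coarse] <- spec$p_in_coarse
  P[same_fine] <- spec$p_in_fine
  rank <- match(role, c("upstream", "middle", "downstream"))
  against <- outer(rank, rank, ">")  # edges pointing against the layer order
  P[against] <- P[against] * (1 - spec$role_bias)
  diag(P) <- 0

  edges <- matrix(stats::rbinom(n * n, 1, P), n, n)
  w <- matrix(0, n, n)
  ne <- sum(edges)
  w[edges == 1] <- stats::rgeom(ne, prob = 1 / spec$weight_mean) + 1

  # gap-junction channel: a fraction of within-fine-block edges becomes
  # symmetric with equal weight (kept within blocks so that role-direction
  # constraints are never violated by the duplication)
  gap <- matrix(0, n, n, dimnames = list(nodes, nodes))
  cand <- which(w > 0 & same_fine, arr.ind = TRUE)
  if (nrow(cand) > 0 && spec$frac_symmetric > 0) {
    pick <- stats::runif(nrow(cand)) < spec$frac_symmetric
    for (r in which(pick)) {
      i <- cand[r, 1]; j <- cand[r, 2]
      wt <- w[i, j]
      w[i, j] <- 0
      gap[i, j] <- gap[j, i] <- max(gap[i, j], wt)
    }
  }
  chem <- w
  dimnames(chem) <- list(nodes, nodes)

  # bridge nodes: rewire a fraction of a node's chemical out-edges uniformly
  # across >= 3 foreign fine blocks (known disruptive targets)
  bridge_nodes <- character(0)
  if (spec$n_bridges > 0 && nf >= 2) {
    deg <- rowSums(chem > 0)
    cand_nodes <- order(deg, decreasing = TRUE)
    cand_nodes <- cand_nodes[deg[cand_nodes] >= 3][seq_len(min(spec$n_bridges,
                                                               n))]
    cand_nodes <- cand_nodes[!is.na(cand_nodes)]
    for (b in cand_nodes) {
      targets_old <- which(chem[b, ] > 0)
      k <- ceiling(spec$bridge_frac * length(targets_old))
      if (k < 1) next
      move <- resample(targets_old, k)
      foreign <- setdiff(seq_len(nf), fine[b])
      blocks <- if (length(foreign) >= 3) resample(foreign, 3) else foreign
      pool <- which(fine %in% blocks & seq_len(n) != b)
      new_t <- resample(pool, k, replace = k > length(pool))
      for (idx in seq_len(k)) {
        wt <- chem[b, move[idx]]
        chem[b, move[idx]] <- 0
        chem[b, new_t[idx]] <- chem[b, new_t[idx]] + wt
      }
      bridge_nodes <- c(bridge_nodes, nodes[b])
    }
  }

  # sinks: zero out-strength (chemical out-edges and all gap contacts removed);
  # drawn from the last fine block, avoiding bridges
  sink_nodes <- character(0)
  if (spec$n_sinks > 0) {
    pool <- setdiff(which(fine == nf), match(bridge_nodes, nodes))
    if (length(pool) < spec$n_sinks)
      pool <- setdiff(seq_len(n), match(bridge_nodes, nodes))
    sinks <- resample(pool, spec$n_sinks)
    chem[sinks, ] <- 0
    gap[sinks, ] <- 0
    gap[, sinks] <- 0
    sink_nodes <- nodes[sinks]
  }

  # every non-sink keeps positive out-strength
  d <- rowSums(chem) + rowSums(gap)
  fix <- setdiff(which(d == 0), match(sink_nodes, nodes))
  for (i in fix) {
    pool <- setdiff(which(fine == fine[i]), c(i, match(sink_nodes, nodes)))
    if (!length(pool)) pool <- setdiff(seq_len(n), c(i, match(sink_nodes, nodes)))
    chem[i, resample(pool, 1)] <- 1
  }

  # S/I/M labels correlated with roles; soma positions correlated with blocks
  type_probs <- list(upstream = c(S = 0.55, I = 0.35, M = 0.10),
                     middle = c(S = 0.15, I = 0.60, M = 0.25),
                     downstream = c(S = 0.05, I = 0.35, M = 0.60))
  node_type <- vapply(role, function(r)
    sample(names(type_probs[[r]]), 1, prob = type_probs[[r]]), "")
  centers <- seq(0.1, 0.9, length.out = nf)
  soma <- pmin(pmax(stats::rnorm(n, centers[fine], 0.08), 0), 1)

  conn <- new_connectome(chem, gap, node_type, soma)
  truth <- list(fine_partition = stats::setNames(fine, nodes),
                coarse_partition = stats::setNames(coarse, nodes),
                role_labels = stats::setNames(role, nodes),
                bridge_nodes = bridge_nodes, sink_nodes = sink_nodes)
  list(connectome = conn, truth = truth)
}

#' Serialise a synthetic spec to YAML
#' @param spec a `synthetic_spec`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path, precision = 15L)
  invisible(path)
}

#' Read a synthetic spec from YAML
#' @param path YAML file written by [write_synthetic_spec()].
#' @return a validated `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  do.call(synthetic_spec, spec[setdiff(names(spec), character(0))])
}
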