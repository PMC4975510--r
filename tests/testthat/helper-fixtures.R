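# Shared fixtures, all built in code.

# X -> Y with 2 chemical synapses, X <-> Y gap junction of weight 1
toy_connectome <- function() {
  nodes <- c("X", "Y")
  chem <- matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE,
                 dimnames = list(nodes, nodes))
  gap <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(nodes, nodes))
  new_connectome(chem, gap)
}

# directed 3-node chain A -> B -> C (C is close to a sink: weak return edge
# keeps the chain connected without teleport-only dynamics at C)
chain3_connectome <- function(w_back = 0) {
  nodes <- c("A", "B", "C")
  chem <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  chem["A", "B"] <- 1
  chem["B", "C"] <- 1
  if (w_back > 0) chem["C", "A"] <- w_back
  new_connectome(chem)
}

# two disjoint directed cliques of sizes n1 and n2 (each strongly connected)
two_cliques_connectome <- function(n1 = 4, n2 = 4) {
  n <- n1 + n2
  A <- matrix(0, n, n)
  A[seq_len(n1), seq_len(n1)] <- 1
  A[n1 + seq_len(n2), n1 + seq_len(n2)] <- 1
  diag(A) <- 0
  dimnames(A) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
  new_connectome(A)
}

# seeded random directed weighted connectome (always weakly connected by a
# directed ring backbone)
random_connectome <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(stats::rbinom(n * n, 1, p) * (1 + stats::rpois(n * n, 1)),
                n, n)
    diag(A) <- 0
    for (i in seq_len(n)) A[i, i %% n + 1] <- max(A[i, i %% n + 1], 1)
    dimnames(A) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
    new_connectome(A)
  })
}

# frozen study fixtures ------------------------------------------------------

# two-level hierarchical planting with clear block contrast: the sweep is
# expected to recover both levels
hierarchical_spec <- function(seed) {
  synthetic_spec(n_nodes = 60, fine_per_coarse = c(2, 2),
                 p_in_fine = 0.5, p_in_coarse = 0.05, p_out = 0.005,
                 n_sinks = 1, n_bridges = 0, seed = seed)
}

# three-layer feed-forward planting for flow-role recovery (thin middle
# layer, flat edge probability, strict direction bias)
feedforward_spec <- function(seed) {
  synthetic_spec(n_nodes = 60, fine_per_coarse = c(2, 1, 2),
                 p_in_fine = 0.4, p_in_coarse = 0.4, p_out = 0.4,
                 role_plan = c("upstream", "upstream", "middle",
                               "downstream", "downstream"),
                 role_bias = 1, n_sinks = 1, n_bridges = 0, seed = seed)
}

# ablation-screen planting: between-block coupling is carried almost entirely
# by the single planted bridge node
screen_spec <- function(seed) {
  synthetic_spec(n_nodes = 40, fine_per_coarse = c(2, 2),
                 p_in_fine = 0.5, p_in_coarse = 0.005, p_out = 0.005,
                 n_sinks = 1, n_bridges = 1, seed = seed)
}

# reduced analysis settings used throughout the synthetic suite
test_times <- function(n = 50) geomspace(0.01, 1000, n)
TEST_ELL <- 20

# adjusted Rand index (independent implementation for agreement checks)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sr <- rowSums(tab)
  sc <- colSums(tab)
  e <- sum(choose(sr, 2)) * sum(choose(sc, 2)) / choose(n, 2)
  (sum(choose(tab, 2)) - e) /
    ((sum(choose(sr, 2)) + sum(choose(sc, 2))) / 2 - e)
}

# brute-force normalised VI from the contingency table (oracle)
vi_oracle <- function(p, q) {
  n <- length(p)
  tab <- table(p, q) / n
  H <- function(f) { f <- f[f > 0]; -sum(f * log(f)) }
  (2 * H(as.numeric(tab)) - H(rowSums(tab)) - H(colSums(tab))) / log(n)
}

# write a wiring table TSV from explicit rows
write_wiring <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}
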