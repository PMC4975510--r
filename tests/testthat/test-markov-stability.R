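test_that("canonical partitions relabel by smallest member index", {
  expect_equal(unname(canonical_partition(c(7, 7, 2, 2, 7))),
               c(1, 1, 2, 2, 1))
  expect_equal(unname(canonical_partition(c("b", "a", "b"))), c(1, 2, 1))
})

test_that("VI attains its exact degenerate values", {
  p <- 1:6                      # singletons
  q <- rep(1, 6)                # all-in-one
  expect_equal(variation_of_information(p, p), 0)
  expect_equal(variation_of_information(p, q), 1)
  expect_equal(variation_of_information(q, q), 0)
})

test_that("VI matches a contingency-table oracle on random partitions", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- sample(1:4, 10, replace = TRUE)
      q <- sample(1:3, 10, replace = TRUE)
    })
    expect_equal(variation_of_information(p, q), vi_oracle(p, q),
                 tolerance = 1e-12)
  }
})

test_that("VI is a metric on canonical partitions", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- sample(1:3, 12, replace = TRUE)
      q <- sample(1:4, 12, replace = TRUE)
      r <- sample(1:2, 12, replace = TRUE)
    })
    expect_equal(variation_of_information(p, q),
                 variation_of_information(q, p))
    expect_gte(variation_of_information(p, q) + 1e-14,
               0)
    # identity of indiscernibles under relabelling
    expect_equal(variation_of_information(p, canonical_partition(p)), 0)
    # triangle inequality
    expect_lte(variation_of_information(p, r),
               variation_of_information(p, q) +
                 variation_of_information(q, r) + 1e-12)
  }
})

test_that("ensemble VI averages the pairwise distances", {
  p1 <- c(1, 1, 2, 2); p2 <- c(1, 2, 1, 2); p3 <- c(1, 1, 1, 2)
  expect_equal(ensemble_vi(list(p1, p1, p1)), 0)
  expect_equal(ensemble_vi(list(p1, p2)), variation_of_information(p1, p2))
  ens <- list(p1, p2, p3, c(1, 2, 2, 2), c(2, 2, 1, 1))
  pairs <- utils::combn(5, 2)
  manual <- mean(apply(pairs, 2, function(ij)
    vi_oracle(ens[[ij[1]]], ens[[ij[2]]])))
  expect_equal(ensemble_vi(ens), manual, tolerance = 1e-12)
  expect_warning(v <- ensemble_vi(list(p1)), "fewer than 2")
  expect_equal(v, 0)
})

test_that("clustered autocovariance has its analytic degenerate forms", {
  cc <- random_connectome(7, seed = 6)
  ts <- build_transition_system(cc)
  # all-in-one: total probability minus stationary product cancels
  for (t in c(0, 1, 10))
    expect_lt(abs(clustered_autocovariance(ts, rep(1, 7), t)[1, 1]), 1e-12)
  # singletons at t = 0: Pi - pi^T pi
  R0 <- clustered_autocovariance(ts, 1:7, 0)
  expect_equal(unname(R0), diag(ts$pi) - tcrossprod(ts$pi),
               tolerance = 1e-10)
})

test_that("clustered autocovariance matches element-wise evaluation", {
  # 4-node, 2-block toy system, hand evaluation with an independent expm
  nodes <- letters[1:4]
  A <- matrix(c(0, 2, 0, 0,
                1, 0, 1, 0,
                0, 0, 0, 3,
                1, 0, 2, 0), 4, 4, byrow = TRUE,
              dimnames = list(nodes, nodes))
  cc <- new_connectome(A)
  ts <- build_transition_system(cc)
  t <- 1.7
  K <- as.matrix(expm::expm(t * (ts$M - diag(4))))
  B <- diag(ts$pi) %*% K - ts$pi %o% ts$pi
  H <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  R_oracle <- t(H) %*% B %*% H
  R <- clustered_autocovariance(ts, c(1, 1, 2, 2), t)
  expect_equal(unname(R), unname(R_oracle), tolerance = 1e-10)
  expect_equal(stability(ts, c(1, 1, 2, 2), t), sum(diag(R_oracle)),
               tolerance = 1e-10)
})

test_that("stability identities hold for any transition system", {
  for (seed in 1:4) {
    cc <- random_connectome(9, seed = seed)
    ts <- build_transition_system(cc)
    expect_lt(abs(stability(ts, rep(1, 9), runif(1, 0, 20))), 1e-12)
    expect_equal(stability(ts, 1:9, 0), 1 - sum(ts$pi^2), tolerance = 1e-10)
  }
})

test_that("a planted bipartition beats random relabellings", {
  for (seed in 1:5) {
    gen <- generate_connectome(synthetic_spec(
      n_nodes = 20, fine_per_coarse = c(1, 1), p_in_fine = 0.6,
      p_in_coarse = 0.05, p_out = 0.05, n_sinks = 0, n_bridges = 0,
      seed = seed))
    ts <- build_transition_system(gen$connectome)
    planted <- gen$truth$fine_partition
    r_planted <- stability(ts, planted, 1)
    shuffled <- withr::with_seed(seed + 100, sample(planted))
    expect_gt(r_planted, stability(ts, shuffled, 1))
  }
})

test_that("the greedy optimum equals exhaustive search on small graphs", {
  fixtures <- list(
    two_cliques_connectome(4, 4),
    two_cliques_connectome(3, 5),
    random_connectome(7, p = 0.4, seed = 11),
    random_connectome(8, p = 0.25, seed = 12),
    chain3_connectome(w_back = 1)
  )
  for (cc in fixtures) {
    ts <- build_transition_system(cc)
    for (t in c(0.5, 1, 5)) {
      opt <- optimise_partition(ts, t, ell = 20, seed = 42)
      exact <- exhaustive_best_partition(ts, t)
      expect_equal(opt$r, exact$r, tolerance = 1e-10)
    }
  }
})

test_that("two disconnected cliques split into the two cliques", {
  cc <- two_cliques_connectome(4, 4)
  ts <- build_transition_system(cc)
  opt <- optimise_partition(ts, 1, ell = 20, seed = 1)
  expect_equal(unname(canonical_partition(opt$best)),
               rep(1:2, each = 4))
})

test_that("a larger ensemble never finds a worse optimum", {
  cc <- random_connectome(20, p = 0.15, seed = 13)
  ts <- build_transition_system(cc)
  r1 <- optimise_partition(ts, 1, ell = 1, seed = 5)$r
  r20 <- optimise_partition(ts, 1, ell = 20, seed = 5)$r
  expect_gte(r20, r1 - 1e-12)
})

test_that("community count shrinks along the sweep before washout", {
  gen <- generate_connectome(hierarchical_spec(3))
  ts <- build_transition_system(gen$connectome)
  sw <- markov_sweep(ts, times = test_times(30), ell = 10, seed = 3)
  m_at <- function(t) sw$n_communities[which.min(abs(sw$times - t))]
  expect_gte(m_at(0.01), m_at(0.5))
  expect_gte(m_at(0.5), m_at(5))
  expect_gte(m_at(5), m_at(50))
})

test_that("the sweep recovers both planted levels over contiguous plateaux", {
  gen <- generate_connectome(hierarchical_spec(1))
  ts <- build_transition_system(gen$connectome)
  sw <- markov_sweep(ts, times = test_times(), ell = TEST_ELL, seed = 1)
  sel <- select_robust_partitions(sw)
  vi_fine <- vapply(sel, function(s)
    variation_of_information(s$partition, gen$truth$fine_partition), 0)
  vi_coarse <- vapply(sel, function(s)
    variation_of_information(s$partition, gen$truth$coarse_partition), 0)
  expect_lt(min(vi_fine), 0.05)
  expect_lt(min(vi_coarse), 0.05)
  # each planted level sits on a plateau spanning more than one grid point
  kf <- which.min(vi_fine)
  expect_gt(sel[[kf]]$t_end, sel[[kf]]$t_start)
})

test_that("a disconnected graph resolves into its components at moderate times", {
  cc <- two_cliques_connectome(5, 5)
  ts <- build_transition_system(cc)
  opt <- optimise_partition(ts, 10, ell = 10, seed = 2)
  expect_equal(unname(canonical_partition(opt$best)), rep(1:2, each = 5))
})

test_that("an unstructured random graph yields no mid-scale robust partition", {
  cc <- random_connectome(40, p = 0.25, seed = 21)
  ts <- build_transition_system(cc)
  sw <- markov_sweep(ts, times = test_times(40), ell = TEST_ELL, seed = 21)
  sel <- select_robust_partitions(sw)
  ms <- vapply(sel, `[[`, 0, "n_communities")
  expect_false(any(ms >= 3 & ms <= 13))
})

test_that("robust-partition selection follows plateaux and dips", {
  # hand-constructed sweep: one persistent partition with a central dip
  n <- 6; nt <- 9
  parts <- matrix(rep(c(1, 1, 2, 2, 3, 3), nt), n, nt)
  parts[, 8:9] <- matrix(c(1:6, c(1, 2, 2, 3, 3, 1)), n, 2)
  sw <- structure(list(
    times = geomspace(0.1, 10, nt), partitions = parts,
    n_communities = apply(parts, 2, function(p) length(unique(p))),
    r = rep(1, nt),
    mean_vi = c(0.2, 0.1, 0.04, 0.01, 0.04, 0.1, 0.2, 0.3, 0.3),
    cross_vi = outer(1:nt, 1:nt, function(i, j)
      ifelse(i == j, 0, ifelse(pmax(i, j) <= 7, 0, 1))),
    ell = 10, seed = 1, nodes = letters[1:n]), class = "markov_sweep")
  sel <- select_robust_partitions(sw)
  expect_length(sel, 1)
  expect_equal(sel[[1]]$t_best, sw$times[4])  # the dip centre
  expect_equal(sel[[1]]$n_communities, 3)
  # a sweep where every time yields a distinct partition selects nothing
  parts2 <- sapply(1:nt, function(k) {
    p <- rep(1:3, each = 2); p[k %% 6 + 1] <- 4 + k %% 2; p
  })
  sw$partitions <- parts2
  sw$n_communities <- apply(parts2, 2, function(p) length(unique(p)))
  sw$cross_vi <- outer(1:nt, 1:nt, function(i, j) ifelse(i == j, 0, 0.5))
  expect_length(select_robust_partitions(sw), 0)
})

test_that("conditional entropy detects hierarchy and its violations", {
  p1 <- c(1, 1, 2, 2, 3, 3, 4, 4)
  p2 <- c(1, 1, 1, 1, 2, 2, 3, 3)        # merges blocks 1+2
  p3 <- c(1, 1, 2, 2, 1, 1, 2, 2)        # merges 1+3 and 2+4: not from p2
  ce <- conditional_entropy_matrix(list(p1, p2, p3))
  expect_equal(ce[1, 2], 0)               # p2 predictable from p1
  expect_equal(ce[1, 3], 0)               # p3 also a coarsening of p1
  expect_gt(ce[2, 3], 0)                  # but not of p2: the one violation
  upper <- ce[upper.tri(ce)]
  expect_equal(sum(upper > 1e-12), 1)
  expect_equal(conditional_entropy_matrix(list(p1, p1))[1, 2], 0)
})
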