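test_that("ablation removes rows and columns and preserves metadata", {
  gen <- generate_connectome(screen_spec(2))
  cc <- gen$connectome
  nd <- cc$nodes[5]
  ab <- ablate(cc, nd)
  expect_equal(length(ab$nodes), length(cc$nodes) - 1)
  expect_false(nd %in% ab$nodes)
  keep <- setdiff(cc$nodes, nd)
  expect_equal(ab$chem, cc$chem[keep, keep])
  expect_equal(ab$gap, cc$gap[keep, keep])
  expect_equal(ab$node_type, cc$node_type[match(keep, cc$nodes)])
  expect_error(ablate(cc, "NOPE"), "NOPE")
})

test_that("sequential and simultaneous ablation commute", {
  cc <- random_connectome(10, seed = 7)
  a1 <- ablate(ablate(cc, "V03"), "V08")
  a2 <- ablate(cc, c("V03", "V08"))
  expect_equal(a1$A, a2$A)
})

test_that("removing a cut vertex shrinks the weak component", {
  # bowtie: two triangles joined through a single cut vertex
  nodes <- paste0("b", 1:5)
  chem <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  chem["b1", "b2"] <- 1; chem["b2", "b3"] <- 1; chem["b3", "b1"] <- 1
  chem["b3", "b4"] <- 1; chem["b4", "b5"] <- 1; chem["b5", "b3"] <- 1
  cc <- new_connectome(chem)
  expect_length(largest_weak_component(cc)$nodes, 5)
  expect_length(largest_weak_component(ablate(cc, "b3"))$nodes, 2)
})

test_that("community variation is zero when the reference is recovered", {
  nodes <- paste0("n", 1:6)
  ref <- stats::setNames(c(1, 1, 2, 2, 3, 3), nodes)
  surv <- nodes[-2]
  parts <- cbind(c(1, 2, 2, 3, 3),          # the restricted reference
                 c(1, 1, 1, 2, 2))
  rownames(parts) <- surv
  sweep_obj <- list(nodes = surv, partitions = parts)
  expect_equal(community_variation(ref, sweep_obj), 0)
})

test_that("community variation is the minimum over sweep times", {
  gen <- generate_connectome(screen_spec(4))
  cc <- gen$connectome
  ts0 <- build_transition_system(cc)
  sw0 <- markov_sweep(ts0, times = test_times(20), ell = 5, seed = 1)
  ref <- stats::setNames(sw0$partitions[, 10], sw0$nodes)
  ab <- ablate(cc, cc$nodes[1])
  sw <- markov_sweep(build_transition_system(ab), times = test_times(20),
                     ell = 5, seed = 2)
  cv <- community_variation(ref, sw)
  # bounded by every single-time comparison, and equal to the oracle min
  surv <- sw$nodes
  per_t <- apply(sw$partitions, 2, function(p) vi_oracle(ref[surv], p))
  expect_equal(cv, min(per_t), tolerance = 1e-12)
  expect_true(all(cv <= per_t + 1e-12))
  expect_gte(cv, 0)
  expect_lte(cv, 1)
})

test_that("the single screen is deterministic and complete", {
  gen <- generate_connectome(synthetic_spec(
    n_nodes = 16, fine_per_coarse = c(1, 1), p_in_fine = 0.5,
    p_in_coarse = 0.1, p_out = 0.1, n_sinks = 0, n_bridges = 0, seed = 5))
  cc <- gen$connectome
  refs <- list(planted = gen$truth$fine_partition)
  scr1 <- single_screen(cc, times = test_times(15), ell = 5, seed = 9,
                        references = refs)
  scr2 <- single_screen(cc, times = test_times(15), ell = 5, seed = 9,
                        references = refs)
  expect_equal(length(scr1$nodes), 16)
  expect_equal(dim(scr1$mean_vi), c(16, 15))
  expect_identical(scr1$cv, scr2$cv)
  expect_identical(scr1$mean_vi, scr2$mean_vi)
  # every per-node sweep lost exactly one node
  expect_true(all(vapply(scr1$sweeps, function(s)
    length(s$nodes), 0L) == 15))
})

test_that("the GP fit recovers flat and symmetric ensembles", {
  times <- geomspace(0.1, 100, 30)
  flat <- matrix(0.3, nrow = 8, ncol = 30)
  fit <- fit_gp_robustness(flat, times)
  expect_lt(max(abs(fit$mu - 0.3)), 1e-6)
  expect_lt(max(fit$sigma), 0.02)
  sym <- rbind(matrix(0.3 + 0.05, 4, 30), matrix(0.3 - 0.05, 4, 30))
  fit2 <- fit_gp_robustness(sym, times)
  expect_lt(max(abs(fit2$mu - 0.3)), 0.01)
  expect_error(fit_gp_robustness(flat[1:2, ], times), "at least 3")
})

test_that("the GP mean tracks a known smooth curve through noise", {
  times <- geomspace(0.1, 100, 40)
  truth <- 0.3 + 0.2 * sin(log(times))
  sigma0 <- 0.05
  n_curves <- 30
  curves <- withr::with_seed(8, t(replicate(n_curves,
    truth + stats::rnorm(40, 0, sigma0))))
  fit <- fit_gp_robustness(curves, times)
  expect_true(all(abs(fit$mu - truth) < 3 * sigma0 / sqrt(n_curves) + 0.01))
  # predictive sd reflects the curve scatter
  expect_true(all(fit$sigma > sigma0 / 2 & fit$sigma < 2 * sigma0))
})

test_that("sustained outliers obey the deviation and span rules", {
  times <- geomspace(0.1, 100, 40)
  base <- matrix(0.3, 20, 40)
  curves <- withr::with_seed(3, base + stats::rnorm(20 * 40, 0, 0.01))
  fit <- fit_gp_robustness(curves, times)
  sh <- fit$sigma  # local predictive sd
  shifted <- rbind(all_up = fit$mu + 3 * sh,
                   mild = fit$mu + 0.5 * sh,
                   brief = fit$mu)
  shifted["brief", 20:22] <- fit$mu[20:22] + 5 * sh[20:22]
  out <- sustained_outliers(fit, shifted, epoch = c(1, 3))
  expect_true("all_up" %in% out)
  expect_false("mild" %in% out)
  # three grid points span ~0.53 log units < ln(3/0.3) required for epoch (0.3, 3)
  out2 <- sustained_outliers(fit, shifted["brief", , drop = FALSE],
                             epoch = c(0.3, 3))
  expect_false("brief" %in% out2)
})

test_that("interpercentile outliers behave on degenerate and clear cases", {
  expect_length(ipr_outliers(stats::setNames(rep(0.2, 50), 1:50)), 0)
  sc <- stats::setNames(c(rep(0.1, 99), 0.9), c(paste0("n", 1:99), "hit"))
  expect_equal(ipr_outliers(sc), "hit")
  expect_error(ipr_outliers(1:5), "at least 10")
})

test_that("uniform scores are rarely flagged as outliers", {
  frac <- withr::with_seed(10, mean(replicate(200, {
    sc <- stats::runif(100)
    length(ipr_outliers(stats::setNames(sc, 1:100))) / 100
  })))
  expect_lt(frac, 0.05)
})

test_that("pair enumeration matches the binomial coefficient", {
  expect_equal(nrow(node_pairs(paste0("n", 1:20))), 190)
  expect_equal(nrow(node_pairs(paste0("n", 1:279))), 38781)
})

test_that("the double screen scores pairs against the additive baseline", {
  gen <- generate_connectome(synthetic_spec(
    n_nodes = 12, fine_per_coarse = c(1, 1), p_in_fine = 0.6,
    p_in_coarse = 0.15, p_out = 0.15, n_sinks = 0, n_bridges = 0, seed = 6))
  cc <- gen$connectome
  refs <- list(planted = gen$truth$fine_partition)
  scr <- single_screen(cc, times = test_times(12), ell = 5, seed = 3,
                       references = refs)
  pairs <- node_pairs(cc$nodes)[1:15, ]
  dbl <- double_screen(cc, scr, pairs, times = test_times(12), ell = 5,
                       seed = 3)
  expect_equal(nrow(dbl), 15)
  expect_true(all(c("cv_pair.planted", "cv_additive.planted") %in%
                    names(dbl)))
  cvs <- stats::setNames(scr$cv[, "planted"], scr$nodes)
  expect_equal(dbl$cv_additive.planted,
               unname((cvs[dbl$node1] + cvs[dbl$node2]) / 2))
  scr_noref <- single_screen(cc, times = test_times(12), ell = 5, seed = 3)
  expect_error(double_screen(cc, scr_noref, pairs), "single_screen")
})

test_that("quantile scores rank an extreme residual at the top", {
  withr::with_seed(4, {
    x <- stats::runif(200)
    y <- x + stats::rnorm(200, 0, 0.05)
  })
  y[1] <- x[1] + 10 * stats::sd(y - x)
  sc <- supra_additive(y, x, top_fraction = 0.01)
  expect_equal(sc$quantile_score[1], max(sc$quantile_score))
  expect_true(sc$top[1])
})

test_that("the median quantile curve matches an independent LAD fit", {
  withr::with_seed(5, {
    x <- stats::runif(300)
    y <- 0.2 + 0.7 * x + stats::rnorm(300, 0, 0.03)
  })
  # independent least-absolute-deviation fit by direct optimisation
  lad <- stats::optim(c(0, 1), function(b) sum(abs(y - b[1] - b[2] * x)))
  fit <- quantreg::rq(y ~ x, tau = 0.5)
  expect_lt(abs(stats::coef(fit)[1] - lad$par[1]), 0.02)
  expect_lt(abs(stats::coef(fit)[2] - lad$par[2]), 0.04)
})

test_that("quantile scores are monotone in the pair score and scale-invariant", {
  withr::with_seed(6, {
    x <- stats::runif(200, 1, 2)
    y <- x + stats::rnorm(200, 0, 0.1)
  })
  sc1 <- supra_additive(y, x)
  # same cv_additive, larger cv_pair => score at least as large
  ord <- order(x)
  near <- ord[1:2]  # two nearly equal predictors
  hi <- which.max(y[near] == max(y[near]))
  expect_gte(sc1$quantile_score[near[hi]] + 1e-9,
             min(sc1$quantile_score[near]))
  # monotone rescaling of the predictor leaves scores unchanged
  sc2 <- supra_additive(y, 10 * x + 3)
  expect_equal(sc1$quantile_score, sc2$quantile_score)
  # degenerate predictor falls back with a warning
  expect_warning(supra_additive(y, rep(1, 200)), "degenerate")
})

test_that("enrichment p-values match the hypergeometric tail", {
  pairs <- node_pairs(paste0("n", 1:12))
  has_n1 <- pairs[, 1] == "n1" | pairs[, 2] == "n1"
  top <- has_n1  # n1 in every top pair, nowhere else
  res <- enrichment(pairs, top)
  p_n1 <- res$p_value[res$node == "n1"]
  # one-sided hypergeometric tail oracle
  k <- sum(has_n1)
  oracle <- 1 - stats::phyper(k - 1, k, nrow(pairs) - k, k)
  expect_equal(p_n1, oracle, tolerance = 1e-10)
  absent <- res$p_value[res$node == "n5"]
  expect_gte(absent, 0.5)
})

test_that("permuted top labels give roughly uniform enrichment p-values", {
  pairs <- node_pairs(paste0("n", 1:15))
  ps <- withr::with_seed(11, replicate(60, {
    top <- sample(c(rep(TRUE, 10), rep(FALSE, nrow(pairs) - 10)))
    res <- enrichment(pairs, top)
    res$p_value[res$node == "n1"]
  }))
  # discrete p-values: check calibration loosely
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.01), 0.1)
})

test_that("screens on the planted-bridge fixture flag the bridge (one seed)", {
  gen <- generate_connectome(screen_spec(8))
  cc <- gen$connectome
  ts <- build_transition_system(cc)
  sw <- markov_sweep(ts, times = test_times(), ell = TEST_ELL, seed = 8)
  sel <- select_robust_partitions(sw)
  refs <- lapply(sel, `[[`, "partition")
  names(refs) <- paste0("P", seq_along(refs))
  scr <- single_screen(cc, times = test_times(), ell = TEST_ELL, seed = 8,
                       references = refs)
  flag_ipr <- unique(unlist(lapply(colnames(scr$cv), function(rf)
    ipr_outliers(stats::setNames(scr$cv[, rf], scr$nodes)))))
  fit <- fit_gp_robustness(rbind(scr$mean_vi, sw$mean_vi), scr$times)
  flag_gp <- unique(unlist(lapply(sel, function(x)
    sustained_outliers(fit, scr$mean_vi, c(x$t_start, x$t_end)))))
  expect_true(gen$truth$bridge_nodes %in% union(flag_ipr, flag_gp))
})
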