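#' Remove nodes from a connectome
#'
#' In-silico ablation: deletes the rows and columns of the adjacency (both
#' synapse channels) belonging to the removed nodes; metadata is preserved
#' for the survivors. Deleting `{i}` then `{j}` equals deleting `{i, j}` at
#' once.
#'
#' @param x a `connectome`.
#' @param nodes character vector of node names to remove.
#' @return the reduced `connectome`.
#' @export
ablate <- function(x, nodes) {
  miss <- setdiff(nodes, x$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
  subset_connectome(x, setdiff(x$nodes, nodes))
}

#' Community variation of an ablated network
#'
#' `CV = min_tau VI(P_ref, P_[i](tau))`: the distance between a reference
#' partition of the intact network and the most similar optimal partition of
#' the ablated network across all Markov times. The reference is first
#' restricted to the surviving nodes (the removed nodes are dropped) and the
#' VI is normalised by the log of the surviving node count -- the only
#' well-defined comparison between partitions of n and n - k nodes.
#'
#' @param reference named partition over the intact node set.
#' @param ablated_sweep a `markov_sweep` of the ablated connectome.
#' @return numeric in `[0, 1]`.
#' @export
community_variation <- function(reference, ablated_sweep) {
  if (is.null(names(reference)))
    stop("'reference' must be a named partition")
  surv <- ablated_sweep$nodes
  if (!all(surv %in% names(reference)))
    stop("ablated sweep contains nodes absent from the reference partition")
  ref <- canonical_partition(reference[surv])
  min(apply(ablated_sweep$partitions, 2, function(p)
    .vi_cpp(as.integer(ref), as.integer(canonical_partition(p)), TRUE)))
}

#' Screen all single-node ablations
#'
#' Runs a full Markov Stability sweep for the deletion of every node,
#' recording the robustness curve `<VI>(t)` and, when reference partitions
#' are supplied, the community-variation score of each deletion against each
#' reference. Per-node seeds are derived deterministically from the master
#' seed, so the screen is order-independent and reproducible. When
#' `checkpoint_dir` is given, each per-node result is cached on disk and an
#' interrupted screen resumes where it stopped.
#'
#' @param x a `connectome`.
#' @param tau teleportation parameter.
#' @param times Markov-time grid for the per-deletion sweeps.
#' @param ell ensemble size per time (screens typically use a reduced 20).
#' @param seed master seed.
#' @param references optional named list of reference partitions of the
#'   intact network.
#' @param checkpoint_dir optional directory for per-node RDS checkpoints.
#' @return an object of class `ablation_screen`: list with `nodes`, `times`,
#'   `mean_vi` (node x time matrix), `cv` (node x reference matrix or NULL),
#'   `sweeps` (per-node best-partition matrices), `seed`.
#' @export
single_screen <- function(x, tau = 0.85, times = geomspace(0.01, 1000, 50),
                          ell = 20, seed = 1, references = NULL,
                          checkpoint_dir = NULL) {
  nodes <- x$nodes
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  one <- function(i) {
    nd <- nodes[i]
    if (!is.null(checkpoint_dir)) {
      f <- file.path(checkpoint_dir, paste0("single_", nd, ".rds"))
      if (file.exists(f)) return(readRDS(f))
    }
    sw <- markov_sweep(build_transition_system(ablate(x, nd), tau),
                       times = times, ell = ell,
                       seed = derive_seed(seed, i))
    res <- list(node = nd, mean_vi = sw$mean_vi, partitions = sw$partitions,
                nodes = sw$nodes,
                cv = if (!is.null(references))
                  vapply(references, community_variation,
                         numeric(1), ablated_sweep = sw))
    if (!is.null(checkpoint_dir)) saveRDS(res, f)
    res
  }
  results <- lapply(seq_along(nodes), one)
  mvi <- do.call(rbind, lapply(results, `[[`, "mean_vi"))
  rownames(mvi) <- nodes
  cv <- if (!is.null(references)) {
    m <- do.call(rbind, lapply(results, `[[`, "cv"))
    dimnames(m) <- list(nodes, names(references))
    m
  }
  structure(list(nodes = nodes, times = times, mean_vi = mvi, cv = cv,
                 references = references,
                 sweeps = lapply(results, function(r)
                   list(partitions = r$partitions, nodes = r$nodes)),
                 ell = ell, seed = seed),
            class = "ablation_screen")
}

#' Fit a Gaussian process to an ensemble of robustness curves
#'
#' Pools the `<VI>(t)` time series of all single-node deletions (plus the
#' intact network) and fits an exact Gaussian-process regression on log
#' Markov time with a squared-exponential kernel plus white noise.
#' Hyperparameters (length-scale, signal sd, noise sd) are chosen by
#' maximising the marginal likelihood; with all curves sharing one grid the
#' likelihood is evaluated through the per-time means and within-time scatter,
#' so the cost scales with the grid size, not the curve count. The returned
#' predictive sd includes the noise term, i.e. it describes the spread of
#' curves around the mean, which is what the sustained-outlier rule needs.
#'
#' @param curves matrix of robustness curves (rows = curves, columns = times)
#'   or a list of equal-length numeric vectors; at least 3 curves.
#' @param times the common Markov-time grid.
#' @return an object of class `gp_fit`: list with `times`, `mu`, `sigma`
#'   (predictive sd including noise), `hyper`.
#' @export
fit_gp_robustness <- function(curves, times) {
  if (is.list(curves)) curves <- do.call(rbind, curves)
  if (nrow(curves) < 3L) stop("need at least 3 curves to fit the GP")
  if (ncol(curves) != length(times))
    stop("curves and times have mismatched lengths")
  x <- log(times)
  R <- nrow(curves)
  ybar <- colMeans(curves)
  s2w <- colSums((t(t(curves) - ybar))^2)  # within-time scatter
  ycen <- mean(ybar)
  yb <- ybar - ycen
  Tn <- length(x)
  D2 <- outer(x, x, "-")^2

  nll <- function(par) {
    l <- exp(par[1]); sf2 <- exp(2 * par[2]); sn2 <- exp(2 * par[3])
    K <- sf2 * exp(-D2 / (2 * l^2))
    C <- K + diag(sn2 / R, Tn)
    ch <- tryCatch(chol(C + diag(1e-10, Tn)), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yb))
    # replicate-aware marginal likelihood: mean component + within-time residuals
    0.5 * sum(yb * alpha) + sum(log(diag(ch))) +
      0.5 * (R - 1) * Tn * log(sn2) + 0.5 * sum(s2w) / sn2
  }
  init <- c(log(max(stats::sd(x), 0.5)),
            log(max(stats::sd(yb), 1e-3)),
            log(max(sqrt(mean(s2w) / max(R - 1, 1)), 1e-4)))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  l <- exp(opt$par[1]); sf2 <- exp(2 * opt$par[2]); sn2 <- exp(2 * opt$par[3])
  K <- sf2 * exp(-D2 / (2 * l^2))
  C <- K + diag(sn2 / R, Tn) + diag(1e-10, Tn)
  alpha <- solve(C, yb)
  mu <- as.numeric(K %*% alpha) + ycen
  var_f <- pmax(sf2 - diag(K %*% solve(C, K)), 0)
  sigma <- sqrt(var_f + sn2)
  structure(list(times = times, mu = mu, sigma = sigma,
                 hyper = c(length_scale = l, signal_sd = sqrt(sf2),
                           noise_sd = sqrt(sn2)),
                 n_curves = R),
            class = "gp_fit")
}

#' Sustained outliers from a Gaussian-process fit
#'
#' Flags curves that deviate from the GP mean by at least `n_sigma`
#' predictive standard deviations over a contiguous run of grid points whose
#' log-time span exceeds `log(t2/t1)`, the log-width of the epoch on which
#' the reference partition is optimal. The span is measured in natural-log
#' Markov time (set `span = "points"` to require the run to cover as many
#' grid points as the epoch instead).
#'
#' @param fit a `gp_fit`.
#' @param curves matrix of curves (rows named by node).
#' @param epoch numeric `c(t1, t2)` within the fitted range.
#' @param n_sigma deviation threshold in predictive sds (default 2).
#' @param span `"log"` (default) or `"points"`.
#' @return character vector of flagged row names.
#' @export
sustained_outliers <- function(fit, curves, epoch, n_sigma = 2,
                               span = c("log", "points")) {
  span <- match.arg(span)
  if (is.list(curves)) curves <- do.call(rbind, curves)
  stopifnot(length(epoch) == 2, epoch[2] > epoch[1])
  need_log <- log(epoch[2] / epoch[1])
  lt <- log(fit$times)
  need_pts <- sum(fit$times >= epoch[1] & fit$times <= epoch[2])
  flagged <- character(0)
  for (r in seq_len(nrow(curves))) {
    dev <- abs(curves[r, ] - fit$mu) >= n_sigma * fit$sigma
    rl <- rle(dev)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in which(rl$values)) {
      long_enough <- if (span == "log")
        lt[ends[k]] - lt[starts[k]] > need_log
      else rl$lengths[k] > need_pts
      if (long_enough) {
        flagged <- c(flagged, rownames(curves)[r] %||% as.character(r))
        break
      }
    }
  }
  flagged
}

#' Interpercentile-range outliers
#'
#' Flags scores exceeding `P90 + |P90 - P10|`, the 90th percentile plus the
#' 10th-to-90th interpercentile range of the score ensemble (strict
#' inequality, so a constant ensemble has no outliers).
#'
#' @param scores named numeric vector (at least 10 values).
#' @return character vector of flagged names.
#' @export
ipr_outliers <- function(scores) {
  if (length(scores) < 10L) stop("need at least 10 scores")
  p90 <- stats::quantile(scores, 0.9, names = FALSE)
  p10 <- stats::quantile(scores, 0.1, names = FALSE)
  thr <- p90 + abs(p90 - p10)
  names(scores)[scores > thr]
}

#' Enumerate unordered node pairs
#' @param nodes character vector of node names.
#' @return 2-column character matrix, one row per unordered pair.
#' @export
node_pairs <- function(nodes) {
  t(utils::combn(nodes, 2))
}

#' Screen double-node ablations
#'
#' For each pair, runs a Markov Stability sweep of the doubly ablated
#' network and computes the pair's community variation against each
#' reference, together with the additive prediction: the mean of the two
#' single-deletion community variations (taken from a completed
#' [single_screen()]).
#'
#' @param x a `connectome`.
#' @param singles a completed `ablation_screen` with `cv` scores.
#' @param pairs 2-column matrix of node-name pairs, or `"all"`.
#' @param tau,times,ell,seed as in [single_screen()].
#' @param checkpoint_dir optional directory for per-pair checkpoints.
#' @return data frame with columns `node1`, `node2`, and per reference `R`:
#'   `cv_pair.R` and `cv_additive.R`.
#' @export
double_screen <- function(x, singles, pairs = "all", tau = 0.85,
                          times = geomspace(0.01, 1000, 50), ell = 20,
                          seed = 1, checkpoint_dir = NULL) {
  if (is.null(singles$cv))
    stop("run single_screen() with reference partitions first")
  if (identical(pairs, "all")) pairs <- node_pairs(x$nodes)
  refs <- colnames(singles$cv)
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  one <- function(k) {
    pr <- pairs[k, ]
    if (!is.null(checkpoint_dir)) {
      f <- file.path(checkpoint_dir,
                     paste0("double_", pr[1], "_", pr[2], ".rds"))
      if (file.exists(f)) return(readRDS(f))
    }
    sw <- markov_sweep(build_transition_system(ablate(x, pr), tau),
                       times = times, ell = ell,
                       seed = derive_seed(seed, 1000L + k))
    cvp <- vapply(refs, function(rf)
      community_variation(singles$references[[rf]], sw), numeric(1))
    if (!is.null(checkpoint_dir)) saveRDS(cvp, f)
    cvp
  }
  if (is.null(singles$references))
    stop("single screen is missing its reference partitions; ",
         "rerun single_screen() with 'references'")
  raw <- vapply(seq_len(nrow(pairs)), one, numeric(length(refs)))
  cvs <- if (length(refs) == 1L) matrix(raw, ncol = 1L) else t(raw)
  colnames(cvs) <- refs
  out <- data.frame(node1 = pairs[, 1], node2 = pairs[, 2],
                    stringsAsFactors = FALSE)
  for (rf in refs) {
    out[[paste0("cv_pair.", rf)]] <- cvs[, rf]
    out[[paste0("cv_additive.", rf)]] <-
      (singles$cv[pairs[, 1], rf] + singles$cv[pairs[, 2], rf]) / 2
  }
  out
}

#' Quantile scores for supra-additive pairs
#'
#' Fits conditional quantile curves of the pair score given the additive
#' prediction on a dense quantile grid (pinball-loss linear quantile
#' regression), monotonically rearranges the fitted curves at each
#' observation so they cannot cross, and assigns each pair the highest
#' quantile level whose fitted value lies at or below the pair's observed
#' score. Pairs in the top `top_fraction` of quantile scores are flagged as
#' supra-additive.
#'
#' @param cv_pair observed double-deletion community variations.
#' @param cv_additive additive predictions (mean of the two singles).
#' @param top_fraction fraction reported as supra-additive (default 0.01).
#' @param quantile_grid grid of quantile levels (default 0.005 steps).
#' @return data frame with `cv_pair`, `cv_additive`, `quantile_score`,
#'   `top` (logical), ordered as given.
#' @export
supra_additive <- function(cv_pair, cv_additive, top_fraction = 0.01,
                           quantile_grid = seq(0.005, 0.995, by = 0.005)) {
  if (length(cv_pair) < 50L) stop("need at least 50 pairs")
  if (length(cv_pair) != length(cv_additive))
    stop("'cv_pair' and 'cv_additive' must have equal length")
  if (stats::sd(cv_additive) < 1e-12) {
    warning("degenerate predictor; falling back to marginal quantiles")
    qs <- stats::quantile(cv_pair, quantile_grid, names = FALSE)
    fitted <- matrix(qs, nrow = length(cv_pair), ncol = length(quantile_grid),
                     byrow = TRUE)
  } else {
    fit <- suppressWarnings(
      quantreg::rq(cv_pair ~ cv_additive, tau = quantile_grid))
    fitted <- stats::predict(fit)
  }
  # monotone rearrangement: sorting the fitted values per observation removes
  # quantile crossings without changing their distribution
  fitted <- t(apply(fitted, 1, sort))
  score <- vapply(seq_along(cv_pair), function(i) {
    below <- which(fitted[i, ] <= cv_pair[i] + 1e-9)
    if (!length(below)) 0 else quantile_grid[max(below)]
  }, numeric(1))
  thr <- stats::quantile(score, 1 - top_fraction, names = FALSE)
  data.frame(cv_pair = cv_pair, cv_additive = cv_additive,
             quantile_score = score, top = score >= thr)
}

#' Per-node enrichment in top supra-additive pairs
#'
#' For each node, builds the 2x2 table (pair contains the node) x (pair in
#' the top set) and computes the one-sided Fisher exact p-value for
#' over-representation. P-values are reported unadjusted.
#'
#' @param pairs 2-column matrix (or data frame) of node pairs.
#' @param top logical vector marking the top pairs.
#' @return data frame with `node`, `n_top`, `n_other`, `p_value`, sorted by
#'   p-value.
#' @export
enrichment <- function(pairs, top) {
  pairs <- as.matrix(pairs)
  stopifnot(nrow(pairs) == length(top))
  nodes <- sort(unique(as.character(pairs)))
  res <- lapply(nodes, function(nd) {
    has <- pairs[, 1] == nd | pairs[, 2] == nd
    tab <- matrix(c(sum(has & top), sum(has & !top),
                    sum(!has & top), sum(!has & !top)), 2, 2)
    data.frame(node = nd, n_top = tab[1, 1], n_other = tab[2, 1],
               p_value = stats::fisher.test(tab, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value), ]
}
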