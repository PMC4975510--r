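#' Build the teleported transition system
#'
#' Constructs the row-stochastic transition matrix of the diffusion used by
#' all flow computations. A non-sink node passes a fraction `tau` of its flow
#' along outgoing edges in proportion to their synapse counts and the
#' remaining `1 - tau` is re-injected uniformly (teleportation, modelling
#' environmental noise); a sink node redistributes uniformly to all nodes.
#' The stationary distribution `pi` (PageRank) is the dominant left
#' eigenvector of `M`, normalised to sum to one.
#'
#' @param x a `connectome`.
#' @param tau teleportation parameter in (0, 1); 0.85 is the customary value.
#' @return an object of class `transition_system` with fields `M`, `tau`,
#'   `pi`, `sink_mask`, `nodes`.
#' @export
build_transition_system <- function(x, tau = 0.85) {
  if (!inherits(x, "connectome")) stop("'x' must be a connectome")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("'tau' must lie strictly between 0 and 1")
  A <- x$A
  n <- nrow(A)
  d <- rowSums(A)
  sink <- d == 0
  M <- matrix((1 - tau) / n, n, n)
  if (any(!sink))
    M[!sink, ] <- M[!sink, ] + tau * A[!sink, , drop = FALSE] / d[!sink]
  if (any(sink))
    M[sink, ] <- 1 / n  # (1 - tau)/n teleportation + tau/n uniform redistribution
  dimnames(M) <- dimnames(A)
  pi <- stationary_distribution(M)
  structure(list(M = M, tau = tau, pi = pi, sink_mask = sink,
                 nodes = x$nodes),
            class = "transition_system")
}

#' @exportS3Method base::print
print.transition_system <- function(x, ...) {
  cat(sprintf("<transition_system> %d nodes, tau = %g, %d sink(s)\n",
              length(x$nodes), x$tau, sum(x$sink_mask)))
  invisible(x)
}

# dominant left eigenvector of a row-stochastic matrix, normalised to sum 1;
# dense eigendecomposition with a power-iteration fallback
stationary_distribution <- function(M, tol = 1e-12) {
  n <- nrow(M)
  if (n == 1L) return(stats::setNames(1, rownames(M)))
  e <- eigen(t(M))
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  pi <- v / sum(v)
  if (any(pi < -1e-10) || max(abs(pi %*% M - pi)) > 1e-8) {
    pi <- rep(1 / n, n)
    for (it in seq_len(100000)) {
      pin <- as.numeric(pi %*% M)
      if (max(abs(pin - pi)) < tol) break
      pi <- pin
    }
    pi <- pin / sum(pin)
  }
  stats::setNames(pmax(pi, 0) / sum(pmax(pi, 0)), rownames(M))
}

# Heat kernels exp(t(M - I)) for a vector of times. A single
# eigendecomposition of M is reused across times when it reconstructs the
# kernel accurately; otherwise each kernel falls back to scaling-and-squaring.
heat_kernels <- function(ts, times) {
  M <- ts$M
  n <- nrow(M)
  I <- diag(n)
  use_eigen <- FALSE
  e <- tryCatch(eigen(M), error = function(e) NULL)
  if (!is.null(e)) {
    Vinv <- tryCatch(solve(e$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      tchk <- stats::median(times)
      K1 <- Re(e$vectors %*% (exp(tchk * (e$values - 1)) * Vinv))
      K2 <- as.matrix(Matrix::expm(tchk * (M - I)))
      if (max(abs(K1 - K2)) < 1e-9) use_eigen <- TRUE
    }
  }
  lapply(times, function(t) {
    K <- if (use_eigen) Re(e$vectors %*% (exp(t * (e$values - 1)) * Vinv))
         else as.matrix(Matrix::expm(t * (M - I)))
    # clip tiny negative entries from finite arithmetic
    K[K < 0 & K > -1e-12] <- 0
    dimnames(K) <- dimnames(M)
    K
  })
}

#' Propagate a flow vector through Markov time
#'
#' Solves the linear diffusion `dphi/dt = phi (M - I)` exactly via the matrix
#' exponential: `phi(t) = phi(0) exp(t(M - I))`.
#'
#' @param ts a `transition_system`.
#' @param phi0 non-negative initial row vector summing to one (no silent
#'   renormalisation is performed).
#' @param times non-negative, strictly increasing Markov times.
#' @return an object of class `flow_state`: list with `times` and `phi`, a
#'   `length(times) x n` matrix of flow vectors.
#' @export
propagate <- function(ts, phi0, times) {
  n <- length(ts$nodes)
  phi0 <- as.numeric(phi0)
  if (length(phi0) != n) stop("'phi0' must have one entry per node")
  if (any(phi0 < 0)) stop("'phi0' must be non-negative")
  if (abs(sum(phi0) - 1) > 1e-8)
    stop("'phi0' must sum to 1 (got ", format(sum(phi0)), ")")
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("'times' must be non-negative and strictly increasing")
  kernels <- heat_kernels(ts, times)
  phi <- do.call(rbind, lapply(kernels, function(K) as.numeric(phi0 %*% K)))
  dimnames(phi) <- list(format(times, trim = TRUE), ts$nodes)
  structure(list(times = times, phi = phi), class = "flow_state")
}
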