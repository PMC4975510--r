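#' Logarithmically spaced grid
#'
#' Markov times are scanned on a geometric grid so that plateaux, which live
#' on log-time, are sampled evenly.
#'
#' @param from,to positive endpoints.
#' @param n number of points.
#' @return numeric vector of length `n`, increasing.
#' @export
geomspace <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# Counter-based seed derivation: a master seed plus a stream index map to a
# reproducible, order-independent child seed (kept below 2^31).
derive_seed <- function(master, index) {
  master <- as.numeric(master) %% 2147483647
  (master * 48271 + 97 * as.numeric(index) + 1) %% 2147483647
}

`%||%` <- function(x, y) if (is.null(x)) y else x
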