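#' Named stimulus scenarios
#'
#' Input-neuron sets for four biologically motivated stimuli, written in the
#' usual left/right shorthand and expanded by [expand_lr()]:
#' `i1` posterior (tail) mechanosensory; `i2` anterior (head) mechanosensory;
#' `i3` posterior chemosensory; `i4` anterior chemosensory.
#'
#' @format named list of character vectors of neuron names.
#' @export
stimulus_scenarios <- list(
  i1 = c("PLML", "PLMR", "PVDL", "PVDR", "PDEL", "PDER"),
  i2 = c("ADEL", "ADER", "ALML", "ALMR", "AQR", "AVM", "BDUL", "BDUR",
         "FLPL", "FLPR", "SIADL", "SIADR"),
  i3 = c("PHAL", "PHAR", "PHBL", "PHBR"),
  i4 = c("ADLL", "ADLR", "ASHL", "ASHR", "ASKL", "ASKR"))

#' Expand left/right neuron-name shorthand
#'
#' A name of the form `"XL/R"` (or `"XR/L"`) expands to the two lateral
#' neurons `XL` and `XR` in the order written; names without the shorthand
#' pass through unchanged.
#'
#' @param names character vector of neuron names or shorthands.
#' @return expanded character vector.
#' @export
expand_lr <- function(names) {
  unlist(lapply(names, function(nm) {
    m <- regmatches(nm, regexec("^(.*)([LR])/([LR])$", nm))[[1]]
    if (length(m) == 4) paste0(m[2], c(m[3], m[4])) else nm
  }), use.names = FALSE)
}

#' Build a localised input flow vector
#'
#' Uniform initial flow over the scenario's input neurons (zero elsewhere,
#' summing to one); per-neuron weights can be supplied to deviate from the
#' maximum-entropy default.
#'
#' @param x a `connectome`.
#' @param input_neurons character vector of input neuron names, or the name
#'   of an entry of [stimulus_scenarios].
#' @param weights optional positive per-neuron weights (normalised to 1).
#' @return named numeric vector `phi0` over all nodes.
#' @export
make_input <- function(x, input_neurons, weights = NULL) {
  if (length(input_neurons) == 1L && input_neurons %in% names(stimulus_scenarios))
    input_neurons <- stimulus_scenarios[[input_neurons]]
  input_neurons <- expand_lr(input_neurons)
  if (!length(input_neurons)) stop("input neuron list is empty")
  miss <- setdiff(input_neurons, x$nodes)
  if (length(miss))
    stop("input neuron(s) not in the connectome: ",
         paste(miss, collapse = ", "))
  phi0 <- stats::setNames(rep(0, length(x$nodes)), x$nodes)
  w <- weights %||% rep(1, length(input_neurons))
  if (any(w <= 0)) stop("input weights must be positive")
  phi0[input_neurons] <- w / sum(w)
  phi0
}

#' Trace stimulus propagation
#'
#' Propagates `phi0` through Markov time and derives the deviation
#' `theta(t) = phi(t) - pi` (which sums to zero and decays to zero) and the
#' relative signal `q_i(t) = phi_i(t) / pi_i`. A node overshoots when its
#' relative signal exceeds its stationary value (`q_max > 1`) on the way to
#' equilibrium; strong responders exceed `1 + 2/3`. Peak times are the grid
#' argmax of `q_i` and are reported only for overshooting nodes.
#'
#' @param ts a `transition_system`.
#' @param phi0 initial flow vector (see [make_input()]).
#' @param times Markov-time grid; the default covers `[0, 200]` with 300
#'   log-spaced points after 0 so that order-one peak times are resolved.
#' @param strong_threshold threshold on `q_max` for the strong-response set.
#' @return an object of class `propagation_trace`: list with `times`, `phi`,
#'   `theta`, `q` (time x node matrices), `q_max`, `peak_time` (named
#'   vectors), `overshoot_set`, `strong_set`, `strong_threshold`.
#' @export
propagation_trace <- function(ts, phi0, times = c(0, geomspace(0.01, 200, 300)),
                              strong_threshold = 1 + 2 / 3) {
  fs <- propagate(ts, phi0, times)
  if (any(ts$pi <= 1e-15))
    stop("stationary distribution has (near-)zero entries; q is undefined")
  theta <- sweep(fs$phi, 2, ts$pi, "-")
  q <- sweep(fs$phi, 2, ts$pi, "/")
  q_max <- apply(q, 2, max)
  peak_idx <- apply(q, 2, which.max)
  # overshoot must exceed stationarity beyond numerical tolerance
  over <- q_max > 1 + 1e-9
  peak_time <- ifelse(over, times[peak_idx], NA_real_)
  names(peak_time) <- ts$nodes
  structure(list(times = times, phi = fs$phi, theta = theta, q = q,
                 q_max = q_max, peak_time = peak_time,
                 overshoot_set = ts$nodes[over],
                 strong_set = ts$nodes[q_max > strong_threshold + 1e-9],
                 strong_threshold = strong_threshold),
            class = "propagation_trace")
}

#' @exportS3Method base::print
print.propagation_trace <- function(x, ...) {
  cat(sprintf("<propagation_trace> %d nodes, t in [%g, %g]\n",
              ncol(x$phi), min(x$times), max(x$times)))
  cat(sprintf("  overshooting: %d, strong (q_max > %.3f): %d\n",
              length(x$overshoot_set), x$strong_threshold,
              length(x$strong_set)))
  invisible(x)
}

#' Strong response nodes of a propagation trace
#'
#' Nodes whose peak relative signal `q_max` exceeds the threshold, with
#' their peak times; `threshold = 1` returns the overshoot set.
#'
#' @param trace a `propagation_trace`.
#' @param threshold `q_max` cutoff (default `1 + 2/3`).
#' @return data frame with `node`, `q_max`, `peak_time`, sorted by peak
#'   time.
#' @export
strong_responders <- function(trace, threshold = 1 + 2 / 3) {
  keep <- trace$q_max > threshold + 1e-9
  out <- data.frame(node = names(trace$peak_time)[keep],
                    q_max = trace$q_max[keep],
                    peak_time = trace$peak_time[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$peak_time), ]
}

#' Histogram of strong-response peak times by group
#'
#' Bins the peak times of strong responders, stratified by a grouping such
#' as the S/I/M type or the flow role, revealing the burst structure of the
#' propagation cascade.
#'
#' @param trace a `propagation_trace`.
#' @param groups named vector mapping nodes to groups (must cover all strong
#'   responders).
#' @param breaks bin edges for the peak times (default: 10 log-spaced bins
#'   over the observed peak range).
#' @param threshold `q_max` cutoff (default: the trace's).
#' @return matrix of counts, groups x bins.
#' @export
peak_histogram <- function(trace, groups, breaks = NULL, threshold = NULL) {
  threshold <- threshold %||% trace$strong_threshold
  sr <- strong_responders(trace, threshold)
  if (!nrow(sr)) stop("no strong responders at this threshold")
  miss <- setdiff(sr$node, names(groups))
  if (length(miss))
    stop("grouping undefined for: ", paste(miss, collapse = ", "))
  if (is.null(breaks)) {
    rng <- range(sr$peak_time)
    breaks <- if (rng[1] == rng[2]) c(rng[1] - 0.5, rng[1] + 0.5)
              else if (rng[1] > 0) exp(seq(log(rng[1]), log(rng[2]),
                                           length.out = 11))
              else seq(rng[1], rng[2], length.out = 11)
    breaks[1] <- breaks[1] - 1e-9
  }
  g <- factor(groups[sr$node])
  bins <- cut(sr$peak_time, breaks, include.lowest = TRUE)
  table(group = g, bin = bins)
}
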