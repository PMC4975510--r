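#' Construct a connectome object
#'
#' A connectome is a directed, weighted network of neurons. Edge weights count
#' synapses and are kept in two channels: `chem` holds directed chemical
#' synapses and `gap` holds electrical gap junctions, which are bidirectional
#' and therefore stored as a symmetric matrix. The total adjacency used by all
#' flow computations is `A = chem + gap`.
#'
#' @param chem n x n non-negative matrix of chemical synapse counts
#'   (row = presynaptic, column = postsynaptic). Dimnames give node names.
#' @param gap n x n symmetric non-negative matrix of gap-junction counts.
#' @param node_type character vector of functional classes, one of
#'   `"S"` (sensory), `"I"` (inter), `"M"` (motor) or `"unknown"`.
#' @param soma_position numeric vector of normalised soma positions in
#'   `[0, 1]`, or `NA` when unknown.
#' @return an object of class `connectome` with fields `nodes`, `A`, `chem`,
#'   `gap`, `node_type`, `soma_position`.
#' @export
new_connectome <- function(chem, gap = NULL, node_type = NULL,
                           soma_position = NULL) {
  chem <- as.matrix(chem)
  n <- nrow(chem)
  if (n == 0L) stop("connectome must contain at least one node")
  if (ncol(chem) != n) stop("'chem' must be square")
  if (is.null(gap)) gap <- matrix(0, n, n, dimnames = dimnames(chem))
  gap <- as.matrix(gap)
  if (!all(dim(gap) == n)) stop("'gap' must match the dimensions of 'chem'")
  nodes <- rownames(chem)
  if (is.null(nodes)) {
    nodes <- sprintf("N%03d", seq_len(n))
    dimnames(chem) <- list(nodes, nodes)
  }
  dimnames(gap) <- dimnames(chem)
  if (any(chem < 0) || any(gap < 0)) stop("synapse counts must be non-negative")
  if (max(abs(gap - t(gap))) > 1e-9) stop("'gap' must be symmetric")
  node_type <- node_type %||% rep("unknown", n)
  soma_position <- soma_position %||% rep(NA_real_, n)
  if (length(node_type) != n || length(soma_position) != n)
    stop("metadata length must equal the number of nodes")
  ok <- is.na(soma_position) | (soma_position >= 0 & soma_position <= 1)
  if (!all(ok)) stop("'soma_position' must lie in [0, 1]")
  structure(
    list(nodes = nodes, A = chem + gap, chem = chem, gap = gap,
         node_type = as.character(node_type),
         soma_position = as.numeric(soma_position)),
    class = "connectome")
}

#' @exportS3Method base::print
print.connectome <- function(x, ...) {
  n <- length(x$nodes)
  cat(sprintf("<connectome> %d nodes, %d chemical synapses, %d gap-junction weight\n",
              n, sum(x$chem), sum(x$gap) / 2))
  comp <- table(factor(x$node_type, levels = c("S", "I", "M", "unknown")))
  cat("  types:", paste(names(comp), comp, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of nodes in a connectome
#' @param x a `connectome`.
#' @return integer node count.
#' @export
n_nodes <- function(x) length(x$nodes)

# Recognised wiring-table type codes. "Send" codes are chemical synapses
# recorded at the presynaptic side; "receive" codes are the mirrored records
# of the same synapses and are dropped to avoid double counting. "EJ" is a
# gap junction; neuromuscular junction rows are skipped.
.chem_send <- c("S", "Sp")
.chem_receive <- c("R", "Rp")
.gap_codes <- "EJ"
.skip_codes <- c("NMJ", "Nmj")

#' Read a wiring table into a connectome
#'
#' Parses a tab-separated synaptic wiring table with columns
#' (neuron_from, neuron_to, type, count). Type codes follow the widely used
#' NeuronConnect convention: `S`/`Sp` add chemical synapses from -> to;
#' `R`/`Rp` are redundant mirrors of send records and are dropped; `EJ` rows
#' are gap junctions, symmetrised by taking, for each unordered pair, the
#' larger of the two directed accumulations (so files listing each junction
#' once or twice per pair both parse to the same symmetric matrix); `NMJ`
#' rows are skipped. Node order is lexicographic by name.
#'
#' @param edge_path path to the TSV wiring table. A header row is detected
#'   and tolerated.
#' @param metadata_path optional CSV with columns `name`, `type`,
#'   `soma_position`; joined by exact name. Unmatched metadata rows trigger a
#'   warning.
#' @return a [new_connectome()] object.
#' @export
read_wiring_table <- function(edge_path, metadata_path = NULL) {
  if (length(readLines(edge_path, n = 1L)) == 0L) stop("no edges")
  raw <- utils::read.delim(edge_path, header = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("no edges")
  # header detection: count column not numeric on row 1
  first_count <- suppressWarnings(as.numeric(raw[1, 4]))
  if (ncol(raw) < 4) stop("wiring table must have 4 columns (from, to, type, count)")
  if (is.na(first_count)) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no edges")
  names(raw)[1:4] <- c("from", "to", "type", "count")
  cnt <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(cnt) | raw$from == "" | raw$to == "" | raw$type == "")
  if (length(bad))
    stop(sprintf("malformed wiring-table row at line %d", bad[1]))
  if (any(cnt < 0))
    stop(sprintf("negative synapse count at line %d", which(cnt < 0)[1]))
  raw$count <- cnt

  keep <- !(raw$type %in% c(.chem_receive, .skip_codes))
  unknown <- setdiff(unique(raw$type), c(.chem_send, .chem_receive,
                                         .gap_codes, .skip_codes))
  if (length(unknown))
    stop("unrecognised type code(s): ", paste(unknown, collapse = ", "))
  tab <- raw[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no edges")

  nodes <- sort(unique(c(raw$from, raw$to)))
  n <- length(nodes)
  chem <- matrix(0, n, n, dimnames = list(nodes, nodes))
  gap <- matrix(0, n, n, dimnames = list(nodes, nodes))
  is_chem <- tab$type %in% .chem_send
  ic <- cbind(match(tab$from, nodes), match(tab$to, nodes))
  for (r in seq_len(nrow(tab))) {
    if (is_chem[r]) chem[ic[r, 1], ic[r, 2]] <- chem[ic[r, 1], ic[r, 2]] + tab$count[r]
    else gap[ic[r, 1], ic[r, 2]] <- gap[ic[r, 1], ic[r, 2]] + tab$count[r]
  }
  gap <- pmax(gap, t(gap))

  node_type <- rep("unknown", n)
  soma <- rep(NA_real_, n)
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    hit <- match(meta$name, nodes)
    if (anyNA(hit))
      warning("metadata rows with no matching neuron: ",
              paste(meta$name[is.na(hit)], collapse = ", "))
    ok <- !is.na(hit)
    node_type[hit[ok]] <- meta$type[ok]
    soma[hit[ok]] <- meta$soma_position[ok]
  }
  new_connectome(chem, gap, node_type, soma)
}

#' Write a connectome to a directory
#'
#' Serialises to the same dialect [read_wiring_table()] reads: an `edges.tsv`
#' wiring table (chemical synapses as `S` rows, gap junctions as one `EJ` row
#' per unordered pair), a `metadata.csv`, and a `manifest.json` recording the
#' conventions used.
#'
#' @param x a `connectome`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(x$chem > 0, arr.ind = TRUE)
  rows <- data.frame(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]],
                     type = "S", count = x$chem[idx],
                     stringsAsFactors = FALSE)
  gidx <- which(x$gap > 0 & upper.tri(x$gap, diag = TRUE), arr.ind = TRUE)
  if (nrow(gidx))
    rows <- rbind(rows, data.frame(from = x$nodes[gidx[, 1]],
                                   to = x$nodes[gidx[, 2]],
                                   type = "EJ", count = x$gap[gidx],
                                   stringsAsFactors = FALSE))
  utils::write.table(rows, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(name = x$nodes, type = x$node_type,
                              soma_position = x$soma_position),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(format = "wiring-table TSV (from, to, type, count)",
         chem_code = "S", gap_code = "EJ",
         gap_convention = "one EJ row per unordered pair, symmetrised on read",
         node_order = "lexicographic"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Restrict a connectome to its largest weakly connected component
#'
#' Direction is ignored when determining connectivity. Size ties are broken
#' in favour of the component containing the lexicographically smallest node
#' name. The operation is idempotent.
#'
#' @param x a `connectome`.
#' @return the induced sub-connectome.
#' @export
largest_weak_component <- function(x) {
  g <- igraph::graph_from_adjacency_matrix(x$A > 0, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    firsts <- vapply(cand, function(k) min(x$nodes[comp$membership == k]), "")
    cand <- cand[order(firsts)][1]
  }
  keep <- which(comp$membership == cand[1])
  subset_connectome(x, x$nodes[keep])
}

# induced sub-connectome on the given node names (order preserved as given)
subset_connectome <- function(x, nodes) {
  i <- match(nodes, x$nodes)
  if (anyNA(i)) stop("unknown node(s): ", paste(nodes[is.na(i)], collapse = ", "))
  new_connectome(x$chem[i, i, drop = FALSE], x$gap[i, i, drop = FALSE],
                 x$node_type[i], x$soma_position[i])
}

#' Out-strengths
#'
#' The out-strength of a node is the total synapse count on its outgoing
#' edges, `d = A 1`. Nodes with zero out-strength are sinks.
#'
#' @param x a `connectome`.
#' @return named numeric vector.
#' @export
out_strengths <- function(x) rowSums(x$A)

#' In-strengths
#' @param x a `connectome`.
#' @return named numeric vector of column sums of `A`.
#' @export
in_strengths <- function(x) colSums(x$A)

#' Edge-type composition of a connectome
#'
#' Classifies every edge by which synapse channels contribute: gap junction
#' only, chemical only, or both. Under the `"directed"` convention an edge is
#' an ordered pair `(i, j)` with `A_ij > 0`; under `"unordered"` it is an
#' unordered pair with a connection in either direction (a pair counts as
#' chemical-only/gap-only/both according to the union of its two directions).
#' Self-loops are excluded.
#'
#' @param x a `connectome`.
#' @param convention `"directed"` (default) or `"unordered"`.
#' @return a list with `n_gap_only`, `n_chem_only`, `n_both`,
#'   `n_edges_total`, and the `convention` used.
#' @export
edge_composition <- function(x, convention = c("directed", "unordered")) {
  convention <- match.arg(convention)
  chem <- x$chem; gap <- x$gap
  diag(chem) <- 0; diag(gap) <- 0
  if (convention == "unordered") {
    chem <- chem + t(chem)
    gap <- gap + t(gap)
    mask <- upper.tri(chem)
  } else {
    mask <- !diag(TRUE, nrow(chem))
  }
  has_c <- chem > 0 & mask
  has_g <- gap > 0 & mask
  res <- list(n_gap_only = sum(has_g & !has_c),
              n_chem_only = sum(has_c & !has_g),
              n_both = sum(has_c & has_g),
              convention = convention)
  res$n_edges_total <- res$n_gap_only + res$n_chem_only + res$n_both
  res
}
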