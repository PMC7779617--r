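#' Weighted directed graph on labelled nodes
#'
#' Dense nonnegative weight matrix with zero diagonal; entry (i, j) is the
#' weight of the edge from node i to node j (for connectivity graphs, the
#' transfer entropy from channel i to channel j). Small negative entries
#' (possible from finite-sample entropy estimates) are clipped to zero and
#' counted in the `n_clipped` attribute.
#'
#' @param weights Square numeric matrix.
#' @param node_labels Character vector of node names; defaults to rownames
#'   or `v1 ... vn`.
#' @return An object of class `weighted_digraph`.
#' @export
weighted_digraph <- function(weights, node_labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights) ||
      nrow(weights) != ncol(weights)) {
    stop("`weights` must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("`weights` must be finite", call. = FALSE)
  }
  n_clipped <- sum(weights < 0)
  weights[weights < 0] <- 0
  diag(weights) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- paste0("v", seq_len(nrow(weights)))
  }
  if (length(node_labels) != nrow(weights)) {
    stop("`node_labels` must have one entry per node", call. = FALSE)
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, node_labels = as.character(node_labels),
                 n_clipped = n_clipped),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat(sprintf("<weighted_digraph> %d nodes, weight range [%.4g, %.4g]\n",
              length(x$node_labels), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Unweighted graph on labelled nodes
#'
#' Boolean adjacency with empty diagonal. `directed = TRUE` (the default)
#' reads entry (i, j) as the edge i -> j; with `directed = FALSE` the
#' adjacency must be symmetric and each unordered pair counts as one edge.
#'
#' @param adjacency Square logical or 0/1 numeric matrix.
#' @param node_labels Optional node names.
#' @param directed Logical flag.
#' @return An object of class `binary_digraph`.
#' @export
binary_digraph <- function(adjacency, node_labels = NULL, directed = TRUE) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("`adjacency` must be a square matrix", call. = FALSE)
  }
  adjacency <- matrix(as.logical(adjacency), nrow(adjacency))
  if (anyNA(adjacency)) stop("`adjacency` must not contain NA", call. = FALSE)
  diag(adjacency) <- FALSE
  directed <- isTRUE(directed)
  if (!directed && !identical(adjacency, t(adjacency))) {
    stop("undirected graph needs a symmetric adjacency", call. = FALSE)
  }
  if (is.null(node_labels)) node_labels <- paste0("v", seq_len(nrow(adjacency)))
  if (length(node_labels) != nrow(adjacency)) {
    stop("`node_labels` must have one entry per node", call. = FALSE)
  }
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency,
                 node_labels = as.character(node_labels),
                 directed = directed),
            class = "binary_digraph")
}

#' @export
print.binary_digraph <- function(x, ...) {
  cat(sprintf("<binary_digraph> %s, %d nodes, %d edges\n",
              if (x$directed) "directed" else "undirected",
              length(x$node_labels), n_edges(x)))
  invisible(x)
}

#' Edge count of a binary graph
#'
#' For a directed graph, the number of ordered pairs with an edge; for an
#' undirected graph, the number of unordered pairs.
#'
#' @param g A `binary_digraph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) {
  s <- sum(g$adjacency)
  if (g$directed) as.integer(s) else as.integer(s / 2)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(
    g$adjacency * 1,
    mode = if (g$directed) "directed" else "undirected")
}

#' Write / read a binary graph as a dense 0/1 delimited matrix
#'
#' The threshold (if any) is recorded in a `#` header comment line.
#'
#' @param g A `binary_digraph`.
#' @param path Output file.
#' @param threshold Optional threshold to record in the header.
#' @return `path`, invisibly.
#' @export
write_digraph_matrix <- function(g, path, threshold = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# binary_digraph directed=%s", g$directed)
  if (!is.null(threshold)) hdr <- sprintf("%s threshold=%.10g", hdr, threshold)
  writeLines(hdr, con)
  writeLines(paste(g$node_labels, collapse = "\t"), con)
  utils::write.table(g$adjacency * 1L, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Edge list of a graph
#'
#' @param g A `binary_digraph` or `weighted_digraph`.
#' @return Data frame with columns `source`, `target` (and `weight` for
#'   weighted graphs); one row per directed edge, or per unordered pair for
#'   undirected graphs.
#' @export
edge_list <- function(g) {
  if (inherits(g, "weighted_digraph")) {
    idx <- which(g$weights > 0, arr.ind = TRUE)
    data.frame(source = g$node_labels[idx[, 1L]],
               target = g$node_labels[idx[, 2L]],
               weight = g$weights[idx],
               stringsAsFactors = FALSE)
  } else {
    adj <- g$adjacency
    if (!g$directed) adj[lower.tri(adj)] <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    data.frame(source = g$node_labels[idx[, 1L]],
               target = g$node_labels[idx[, 2L]],
               stringsAsFactors = FALSE)
  }
}

#' Write / read a weighted digraph as a delimited matrix with a name header
#'
#' @param w A `weighted_digraph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(w, path) {
  df <- as.data.frame(w$weights)
  names(df) <- w$node_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  weighted_digraph(as.matrix(df), node_labels = names(df))
}
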