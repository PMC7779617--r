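#' Rank nodes by receiving or sending capability
#'
#' Orders nodes by descending in-degree (`mode = "receive"`), descending
#' out-degree (`mode = "send"`), or descending total degree
#' (`mode = "node"`, for the undirected node-removal baseline). Ties break
#' by ascending node index so the ordering is deterministic and
#' label-stable. The ranking is computed once on the graph as given.
#'
#' @param g A `binary_digraph`.
#' @param mode One of `"receive"`, `"send"`, `"node"`.
#' @return Integer vector of node indices, most important first.
#' @export
rank_nodes <- function(g, mode = c("receive", "send", "node")) {
  mode <- match.arg(mode)
  deg <- switch(mode,
                receive = colSums(g$adjacency),
                send    = rowSums(g$adjacency),
                node    = rowSums(g$adjacency | t(g$adjacency)))
  order(-deg, seq_along(deg))
}

#' Receiving-edge / sending-edge removal sequence
#'
#' Deliberate attack on a directed graph. Nodes are ranked once by
#' in-degree (`"receive"`) or out-degree (`"send"`); step k deletes from
#' the current residual every edge pointing to (receive) or leaving (send)
#' the k-th ranked node. After n steps every node has lost the
#' corresponding capability, so the last residual network is edgeless. The
#' residual sequence (1st residual network ... nth) is the raw material for
#' the feature tensor.
#'
#' @param g A directed `binary_digraph`.
#' @param mode `"receive"` or `"send"`.
#' @param rank `"static"` (default; rank once on the original graph, as the
#'   attack is defined) or `"dynamic"` (re-rank on each residual).
#' @return An object of class `removal_sequence`: list with `mode`, `order`
#'   (node indices in removal order), `residuals` (list of n
#'   `binary_digraph`s) and the original graph.
#' @export
edge_removal_sequence <- function(g, mode = c("receive", "send"),
                                  rank = c("static", "dynamic")) {
  mode <- match.arg(mode)
  rank <- match.arg(rank)
  if (!g$directed) stop("edge removal is defined for directed graphs",
                        call. = FALSE)
  n <- length(g$node_labels)
  adj <- g$adjacency
  order_static <- rank_nodes(g, mode)
  order_used <- integer(n)
  removed <- logical(n)
  residuals <- vector("list", n)
  for (k in seq_len(n)) {
    v <- if (rank == "static") {
      order_static[k]
    } else {
      cur <- binary_digraph(adj, g$node_labels)
      cand <- rank_nodes(cur, mode)
      cand[!removed[cand]][1L]
    }
    order_used[k] <- v
    removed[v] <- TRUE
    if (mode == "receive") adj[, v] <- FALSE else adj[v, ] <- FALSE
    residuals[[k]] <- binary_digraph(adj, g$node_labels)
  }
  structure(list(mode = mode, order = order_used, residuals = residuals,
                 original = g),
            class = "removal_sequence")
}

#' Node-removal sequence on an undirected graph
#'
#' Classical deliberate-attack baseline: at each step the currently
#' highest-degree node (ties by lowest index) is deleted together with all
#' incident edges, and degrees are recomputed on the residual before the
#' next step. Deleted nodes stay in the matrix as isolated nodes so all
#' residuals share the node set.
#'
#' @param g An undirected `binary_digraph`.
#' @return A `removal_sequence` with `mode = "node"`.
#' @export
node_removal_sequence <- function(g) {
  if (g$directed) stop("node removal baseline expects an undirected graph",
                       call. = FALSE)
  n <- length(g$node_labels)
  adj <- g$adjacency
  removed <- logical(n)
  order_used <- integer(n)
  residuals <- vector("list", n)
  for (k in seq_len(n)) {
    deg <- rowSums(adj)
    deg[removed] <- -1
    v <- order(-deg, seq_len(n))[1L]
    order_used[k] <- v
    removed[v] <- TRUE
    adj[v, ] <- FALSE
    adj[, v] <- FALSE
    residuals[[k]] <- binary_digraph(adj, g$node_labels, directed = FALSE)
  }
  structure(list(mode = "node", order = order_used, residuals = residuals,
                 original = g),
            class = "removal_sequence")
}

#' @export
print.removal_sequence <- function(x, ...) {
  cat(sprintf("<removal_sequence> mode=%s, %d steps, edges %d -> %d\n",
              x$mode, length(x$residuals), n_edges(x$original),
              n_edges(x$residuals[[length(x$residuals)]])))
  invisible(x)
}

#' Topological feature curves along a removal sequence
#'
#' Average clustering coefficient and network efficiency of the original
#' graph (step 0) and of every residual network (steps 1 ... n).
#'
#' @param seq A `removal_sequence`.
#' @return Data frame with columns `step` (0 ... n), `mode`,
#'   `avg_clustering`, `efficiency`, `edges_remaining`.
#' @export
feature_curves <- function(seq) {
  graphs <- c(list(seq$original), seq$residuals)
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    data.frame(step = i - 1L, mode = seq$mode,
               avg_clustering = avg_clustering(g),
               efficiency = efficiency(g),
               edges_remaining = n_edges(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
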