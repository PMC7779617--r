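#' Node degrees and averages
#'
#' For a directed graph returns per-node in-, out- and total degree; for an
#' undirected graph the ordinary degree. Bookkeeping identity: the sums of
#' in- and out-degrees both equal the number of directed edges.
#'
#' @param g A `binary_digraph`.
#' @return List with per-node vectors (`in_degree`, `out_degree`, `degree`)
#'   and scalar averages (`avg_in_degree`, `avg_out_degree`, `avg_degree`).
#' @examples
#' g <- random_graph(200, 787, seed = 1)
#' degrees(g)$avg_in_degree   # 3.935
#' @export
degrees <- function(g) {
  adj <- g$adjacency
  if (g$directed) {
    ind <- colSums(adj)
    outd <- rowSums(adj)
    list(in_degree = ind, out_degree = outd, degree = ind + outd,
         avg_in_degree = mean(ind), avg_out_degree = mean(outd),
         avg_degree = mean(ind + outd))
  } else {
    d <- rowSums(adj)
    list(degree = d, avg_degree = mean(d))
  }
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local neighbour-interconnection density. For an
#' undirected graph, node i with neighbour set of size k contributes
#' `2 e_i / (k (k - 1))` where `e_i` is the number of edges among its
#' neighbours. For a directed graph the neighbour set is the union of
#' predecessors and successors, `e_i` counts each directed edge among the
#' neighbours once, and the factor 2 is dropped. Nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param g A `binary_digraph`.
#' @return Average clustering coefficient in \[0, 1\].
#' @export
avg_clustering <- function(g) {
  mean(local_clustering(g))
}

#' @rdname avg_clustering
#' @return `local_clustering` returns the per-node coefficients.
#' @export
local_clustering <- function(g) {
  adj <- g$adjacency
  n <- nrow(adj)
  if (n == 0L) return(numeric(0))
  nbr <- if (g$directed) adj | t(adj) else adj
  vapply(seq_len(n), function(i) {
    nb <- which(nbr[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    e <- sum(adj[nb, nb])
    if (!g$directed) e <- e / 2
    num <- if (g$directed) e else 2 * e
    num / (k * (k - 1))
  }, numeric(1))
}

#' Network efficiency
#'
#' Mean of the inverse shortest-path length over all ordered node pairs
#' (i, j), i != j. Path lengths are unweighted; for a directed graph paths
#' follow edge direction. An unreachable pair contributes 0, so efficiency
#' lies in \[0, 1\] and equals 1 exactly for a complete graph.
#'
#' @param g A `binary_digraph` with at least 2 nodes.
#' @return Network efficiency in \[0, 1\].
#' @export
efficiency <- function(g) {
  n <- length(g$node_labels)
  if (n < 2L) stop("efficiency needs at least 2 nodes", call. = FALSE)
  if (n_edges(g) == 0L) return(0)
  d <- igraph::distances(as_igraph(g), mode = "out")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Standard topological feature record for one graph
#'
#' @param g A `binary_digraph`.
#' @return One-row data frame with average degree(s), average clustering
#'   coefficient and network efficiency.
#' @export
graph_features <- function(g) {
  deg <- degrees(g)
  base <- data.frame(n_nodes = length(g$node_labels), n_edges = n_edges(g),
                     avg_degree = deg$avg_degree)
  if (g$directed) {
    base$avg_in_degree <- deg$avg_in_degree
    base$avg_out_degree <- deg$avg_out_degree
  }
  base$avg_clustering <- avg_clustering(g)
  base$efficiency <- if (length(g$node_labels) >= 2L) efficiency(g) else 0
  base
}
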