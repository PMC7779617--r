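# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: shortest paths by min-plus
# Floyd-Warshall, clustering by direct neighbour enumeration, transfer
# entropy by literal summation over joint cells.

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- matrix(Inf, n, n)
  D[adj] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  iv <- 1 / D
  diag(iv) <- 0
  iv[!is.finite(iv)] <- 0
  sum(iv) / (n * (n - 1))
}

oracle_clustering_directed <- function(adj) {
  n <- nrow(adj)
  und <- adj | t(adj)
  tot <- 0
  for (i in seq_len(n)) {
    nb <- which(und[i, ])
    k <- length(nb)
    if (k >= 2) tot <- tot + sum(adj[nb, nb]) / (k * (k - 1))
  }
  tot / n
}

oracle_clustering_undirected <- function(adj) {
  n <- nrow(adj)
  tot <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k >= 2) tot <- tot + 2 * (sum(adj[nb, nb]) / 2) / (k * (k - 1))
  }
  tot / n
}

# Literal conditional-probability summation of the transfer-entropy
# functional over an explicit (future, target-past, source-past) joint.
oracle_te_joint <- function(joint) {
  dm <- dim(joint)
  p_xy <- apply(joint, c(2, 3), sum)
  p_fx <- apply(joint, c(1, 2), sum)
  p_x <- apply(joint, 2, sum)
  te <- 0
  for (f in seq_len(dm[1])) for (i in seq_len(dm[2])) {
    for (j in seq_len(dm[3])) {
      pc <- joint[f, i, j]
      if (pc > 0) {
        te <- te + pc * log2((pc / p_xy[i, j]) / (p_fx[f, i] / p_x[i]))
      }
    }
  }
  te
}

# Exact joint distribution of (y_{t+1}, y_t, x_t) for the noisy-copy
# process: x iid fair Bernoulli, y_{t+1} = x_t flipped w.p. eps. y_t is
# independent of x_t (it copies x_{t-1}).
copy_pair_joint <- function(eps) {
  joint <- array(0, c(2, 2, 2))
  for (yf in 0:1) for (yp in 0:1) for (xp in 0:1) {
    p_trans <- if (yf == xp) 1 - eps else eps
    joint[yf + 1, yp + 1, xp + 1] <- 0.25 * p_trans
  }
  joint
}

# All digraph adjacency matrices on n nodes (2^(n(n-1)) of them).
all_digraphs <- function(n) {
  offdiag <- which(diag(n) == 0)
  m <- length(offdiag)
  lapply(0:(2^m - 1), function(code) {
    bits <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    adj <- matrix(FALSE, n, n)
    adj[offdiag] <- bits
    adj
  })
}

random_adj <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1)
  adj <- matrix(rbinom(n * n, 1, p) == 1, n, n)
  diag(adj) <- FALSE
  adj
}

# Small deterministic toy weighted digraph set for group-network tests
toy_weighted <- function(weights, labels = NULL) {
  weighted_digraph(weights, node_labels = labels)
}
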