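test_that("rank_nodes sorts by capability with index tie-breaks", {
  # in-degrees A:2 B:3 C:4 D:1 -> receive order C B A D
  adj5 <- matrix(0, 5, 5)
  adj5[cbind(c(2, 3), 1)] <- 1                  # A: 2
  adj5[cbind(c(1, 3, 5), 2)] <- 1               # B: 3
  adj5[cbind(c(1, 2, 4, 5), 3)] <- 1            # C: 4
  adj5[cbind(5, 4)] <- 1                        # D: 1
  g <- binary_digraph(adj5, node_labels = c("A", "B", "C", "D", "E"))
  ord <- rank_nodes(g, "receive")
  expect_equal(g$node_labels[ord][1:4], c("C", "B", "A", "D"))

  # all-equal degrees fall back to index order
  ring <- binary_digraph(ring_coupling(5, 1) > 0)
  expect_equal(rank_nodes(ring, "receive"), 1:5)
  empty <- binary_digraph(matrix(0, 4, 4))
  expect_equal(rank_nodes(empty, "send"), 1:4)
  expect_error(rank_nodes(g, "sideways"))
})

test_that("edge removal strips capabilities and ends edgeless", {
  # star: all edges point to the hub -> first step empties the graph
  star <- matrix(0, 5, 5); star[2:5, 1] <- 1
  s <- edge_removal_sequence(binary_digraph(star), "receive")
  expect_equal(n_edges(s$residuals[[1]]), 0L)

  # complete digraph n=3: edge counts 6 -> 4 -> 2 -> 0
  full <- binary_digraph(matrix(1, 3, 3))
  for (mode in c("receive", "send")) {
    sq <- edge_removal_sequence(full, mode)
    expect_equal(vapply(sq$residuals, n_edges, integer(1)), c(4L, 2L, 0L))
  }

  set.seed(16)
  for (rep in 1:20) {
    g <- random_graph(8, sample(0:40, 1), seed = rep)
    for (mode in c("receive", "send")) {
      sq <- edge_removal_sequence(g, mode)
      n <- 8
      expect_length(sq$residuals, n)
      # nested residual edge sets
      for (k in 1:(n - 1)) {
        expect_true(all(sq$residuals[[k + 1]]$adjacency <=
                          sq$residuals[[k]]$adjacency))
      }
      # last residual is isolated nodes; removals account for every edge
      expect_equal(n_edges(sq$residuals[[n]]), 0L)
      counts <- c(n_edges(g), vapply(sq$residuals, n_edges, integer(1)))
      expect_equal(sum(-diff(counts)), n_edges(g))
      # after step k the k ranked nodes have lost the capability
      for (k in c(2, n)) {
        done <- sq$order[1:k]
        res <- sq$residuals[[k]]$adjacency
        if (mode == "receive") expect_equal(sum(res[, done]), 0)
        else expect_equal(sum(res[done, ]), 0)
      }
    }
  }
  expect_error(edge_removal_sequence(
    binary_digraph(matrix(0, 3, 3), directed = FALSE) , "receive"),
    "directed")
})

test_that("node removal recomputes degrees each step", {
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  s <- node_removal_sequence(binary_digraph(path, directed = FALSE))
  expect_equal(s$order[1], 2L)
  expect_equal(n_edges(s$residuals[[1]]), 0L)

  # complete undirected n=4: 6 -> 3 -> 1 -> 0 -> 0
  full <- binary_digraph(matrix(1, 4, 4) - diag(4), directed = FALSE)
  sq <- node_removal_sequence(full)
  expect_equal(vapply(sq$residuals, n_edges, integer(1)), c(3L, 1L, 0L, 0L))

  empty <- binary_digraph(matrix(0, 3, 3), directed = FALSE)
  se <- node_removal_sequence(empty)
  expect_true(all(vapply(se$residuals, n_edges, integer(1)) == 0L))

  # dynamic re-ranking can depart from the static order
  set.seed(17)
  g <- random_graph(10, 40, seed = 99)
  dyn <- edge_removal_sequence(g, "receive", rank = "dynamic")
  expect_equal(n_edges(dyn$residuals[[10]]), 0L)
})

test_that("feature curves start at the original graph and end at (0, 0)", {
  g <- random_graph(8, 30, seed = 5)
  sq <- edge_removal_sequence(g, "receive")
  cv <- feature_curves(sq)
  expect_equal(nrow(cv), 9L)
  expect_equal(cv$avg_clustering[1], avg_clustering(g))
  expect_equal(cv$efficiency[1], efficiency(g))
  expect_equal(cv$avg_clustering[9], 0)
  expect_equal(cv$efficiency[9], 0)
  expect_true(all(diff(cv$edges_remaining) <= 0))
})

test_that("efficiency is non-increasing along removal sequences", {
  set.seed(18)
  for (rep in 1:100) {
    g <- random_graph(7, sample(5:35, 1), seed = 1000 + rep)
    for (mode in c("receive", "send")) {
      cv <- feature_curves(edge_removal_sequence(g, mode))
      expect_true(all(diff(cv$efficiency) <= 1e-12))
    }
  }
})

test_that("edge removal separates digraph pairs that node removal does not", {
  # matched random digraphs: same node and edge count, similar global
  # features, but different wiring
  gC <- random_graph(40, 160, seed = 31)
  gD <- random_graph(40, 160, seed = 32)
  undirected_view <- function(g) {
    binary_digraph(g$adjacency | t(g$adjacency), directed = FALSE)
  }
  node_gap <- max(abs(
    feature_curves(node_removal_sequence(undirected_view(gC)))$efficiency -
    feature_curves(node_removal_sequence(undirected_view(gD)))$efficiency))
  edge_gap <- max(abs(
    feature_curves(edge_removal_sequence(gC, "receive"))$efficiency -
    feature_curves(edge_removal_sequence(gD, "receive"))$efficiency))
  # the directed attack exposes a larger separation than the undirected
  # node-removal baseline on the same pair
  expect_gt(edge_gap, node_gap)
})
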