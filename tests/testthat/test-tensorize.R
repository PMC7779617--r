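rand_tensor <- function(dims, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(dims)), dims)
}

test_that("unfold / fold / ttm are mutually consistent", {
  a <- rand_tensor(c(3, 4, 2, 2, 4))
  for (k in 1:5) {
    expect_equal(fold(unfold(a, k), k, dim(a)), a)
  }
  # ttm against naive elementwise contraction on a small case
  b <- rand_tensor(c(2, 3, 2), seed = 2)
  m <- matrix(rnorm(6), 2, 3)
  out <- ttm(b, m, 2)
  naive <- array(0, c(2, 2, 2))
  for (i in 1:2) for (r in 1:2) for (k in 1:2) {
    naive[i, r, k] <- sum(m[r, ] * b[i, , k])
  }
  expect_equal(out, naive)
})

test_that("feature tensor has the documented shape and cell semantics", {
  set.seed(23)
  mk_conn <- function(n) {
    out <- lapply(names(rhythm_bands()), function(b)
      weighted_digraph(matrix(runif(n * n, 0, 0.01), n, n)))
    names(out) <- names(rhythm_bands())
    out
  }
  conn <- mk_conn(4)
  grid <- threshold_grid(0, 0.009, 0.003)
  q <- build_feature_tensor(conn, grid)
  expect_equal(dim(q), c(3L, 4L, 2L, 2L, 4L))
  expect_true(all(is.finite(q)))
  expect_true(all(q >= 0 & q <= 1))

  # cell-by-cell oracle: recompute every entry independently
  modes <- c("receive", "send")
  for (i in seq_along(grid)) for (r in 1:4) {
    w <- conn[[names(rhythm_bands())[r]]]
    g <- binarize(w, grid[i])
    for (a in 1:2) {
      sq <- edge_removal_sequence(g, modes[a])
      for (j in 1:4) {
        expect_equal(q[i, j, a, 1, r], avg_clustering(sq$residuals[[j]]))
        expect_equal(q[i, j, a, 2, r], efficiency(sq$residuals[[j]]))
      }
    }
  }

  # a threshold above every weight yields an all-zero slab
  big <- threshold_grid(0, 0.03, 0.01)
  qb <- build_feature_tensor(conn, big)
  expect_equal(max(abs(qb[3, , , , ])), 0)

  # inconsistent node counts across rhythms are rejected
  bad <- conn; bad$delta <- weighted_digraph(matrix(0.001, 3, 3))
  expect_error(build_feature_tensor(bad, grid), "node count")
})

test_that("Tucker-HOOI reaches exact fits where they exist", {
  # full core shape: no truncation, psi = 1
  q <- rand_tensor(c(3, 4, 2, 2, 3), seed = 3)
  tk <- tucker_hooi(q, dim(q))
  expect_equal(tk$fit, 1, tolerance = 1e-10)
  expect_equal(tucker_reconstruct(tk), q, tolerance = 1e-8)

  # rank-1 tensor recovered exactly by a (1,...,1) core
  set.seed(4)
  us <- lapply(c(3, 4, 2, 2, 4), rnorm)
  t1 <- array(Reduce(`%o%`, us), c(3, 4, 2, 2, 4))
  tk1 <- tucker_hooi(t1, c(1, 1, 1, 1, 1))
  expect_equal(tk1$fit, 1, tolerance = 1e-6)

  # factors are column-orthonormal
  for (u in tk1$factors) {
    expect_equal(crossprod(u), diag(ncol(u)), tolerance = 1e-8)
  }

  expect_error(tucker_hooi(q, c(5, 4, 2, 2, 3)), "exceed")

  # all-zero tensor: defined as fully explained
  z <- tucker_hooi(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(z$fit, 1)
})

test_that("psi equals the explicit reconstruction fit and is monotone", {
  q <- rand_tensor(c(5, 4, 3, 2, 3), seed = 5)
  tk <- tucker_hooi(q, c(3, 2, 2, 2, 2))
  psi_oracle <- 1 - sum((q - tucker_reconstruct(tk))^2) / sum(q^2)
  expect_equal(tk$fit, psi_oracle, tolerance = 1e-10)
  expect_equal(fraction_explained(q, tk), psi_oracle, tolerance = 1e-10)
  # the alternative printed form coincides at a perfect fit
  tkf <- tucker_hooi(q, dim(q))
  expect_equal(fraction_explained(q, tkf, "ratio"), 1, tolerance = 1e-8)

  # nested-subspace monotonicity in each mode
  base_shape <- c(2, 2, 2, 2, 2)
  base_fit <- tucker_hooi(q, base_shape)$fit
  for (k in 1:5) {
    if (base_shape[k] + 1 > dim(q)[k]) next
    grown <- base_shape
    grown[k] <- grown[k] + 1
    expect_gte(tucker_hooi(q, grown)$fit, base_fit - 1e-8)
  }

  # HOOI improves on (or matches) its HOSVD initialisation
  factors0 <- epitensor:::hosvd_factors(q, c(3, 2, 2, 2, 2))
  hosvd_fit <- epitensor:::core_norm2(q, factors0) / sum(q^2)
  expect_gte(tk$fit, hosvd_fit - 1e-10)
})

test_that("core shape grid enumerates the complete-trial candidates", {
  expect_length(core_shape_grid(600, 16), 192L)
  expect_length(core_shape_grid(3, 3), 12L)
  cands <- core_shape_grid(600, 16)
  expect_true(any(vapply(cands, function(s)
    identical(s, c(8L, 6L, 2L, 2L, 4L)), logical(1))))
  # every candidate respects the 1 < lambda < 10 bounds and fixed modes
  for (s in cands) {
    expect_true(all(s[1:2] >= 2 & s[1:2] <= 9))
    expect_equal(s[3:4], c(2L, 2L))
    expect_true(s[5] %in% 2:4)
  }
})

test_that("core reshape is a documented bijection", {
  core <- rand_tensor(c(8, 6, 2, 2, 4), seed = 6)
  v <- reshape_core(core)
  expect_length(v, 768L)
  expect_equal(unreshape_core(v, dim(core)), core)

  expect_length(reshape_core(array(5, c(1, 1, 1, 1, 1))), 1L)

  # first mode varies slowest, last fastest
  idx <- array(seq_len(2 * 2 * 2), c(2, 2, 2))
  v3 <- reshape_core(idx)
  expect_equal(v3[1:2], c(idx[1, 1, 1], idx[1, 1, 2]))
  expect_equal(v3[8], idx[2, 2, 2])
})
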