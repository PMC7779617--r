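test_that("random_graph draws exactly the requested edges, deterministically", {
  g <- random_graph(200, 787, seed = 1)
  expect_equal(n_edges(g), 787L)
  deg <- degrees(g)
  expect_equal(deg$avg_in_degree, 3.935)
  expect_equal(deg$avg_out_degree, 3.935)
  expect_equal(sum(deg$in_degree), sum(deg$out_degree))
  expect_equal(sum(deg$in_degree), 787)

  # byte-identical regeneration under the same seed
  expect_identical(g$adjacency, random_graph(200, 787, seed = 1)$adjacency)
  expect_false(identical(g$adjacency, random_graph(200, 787, seed = 2)$adjacency))

  # degenerate and saturated cases
  empty <- random_graph(5, 0, seed = 1)
  expect_equal(n_edges(empty), 0L)
  expect_equal(efficiency(empty), 0)
  full <- random_graph(4, 12, seed = 1)
  expect_true(all(full$adjacency[diag(4) == 0]))
  expect_error(random_graph(4, 13, seed = 1), "exceeds")

  # undirected variant stays symmetric and counts unordered pairs
  gu <- random_graph(10, 20, directed = FALSE, seed = 3)
  expect_identical(gu$adjacency, t(gu$adjacency))
  expect_equal(n_edges(gu), 20L)
  expect_error(random_graph(10, 46, directed = FALSE, seed = 1), "exceeds")
})

test_that("noisy_copy_pair matches its closed-form transfer entropy", {
  expect_error(noisy_copy_pair(100, 1.2), "probability")

  # closed form via the independent brute-force joint oracle
  for (eps in c(0, 0.1, 0.25, 0.5)) {
    pair <- noisy_copy_pair(1000, eps, seed = 5)
    expect_equal(pair$te_true, oracle_te_joint(copy_pair_joint(eps)),
                 tolerance = 1e-12)
  }
  expect_equal(noisy_copy_pair(100, 0.5, seed = 1)$te_true, 0)
  expect_equal(noisy_copy_pair(100, 0, seed = 1)$te_true, 1)

  # generator obeys the copy law exactly at eps = 0
  pair <- noisy_copy_pair(5000, 0, seed = 2)
  expect_equal(pair$y[-1], pair$x[-5000])
  # and is reproducible
  expect_identical(pair, noisy_copy_pair(5000, 0, seed = 2))
})

test_that("plug-in TE estimate on copy pairs converges to the closed form", {
  p <- te_params(n_bins = 2)
  for (eps in c(0, 0.1, 0.25, 0.5)) {
    pair <- noisy_copy_pair(1e5, eps, seed = 11)
    est <- as.numeric(transfer_entropy(pair$y, pair$x, p))
    expect_lt(abs(est - pair$te_true), 0.05)
  }
  # average absolute error shrinks from 1e3 to 1e5 samples
  errs <- sapply(1:20, function(s) {
    sapply(c(1e3, 1e5), function(n) {
      pr <- noisy_copy_pair(n, 0.1, seed = s)
      abs(as.numeric(transfer_entropy(pr$y, pr$x, p)) - pr$te_true)
    })
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("synth_cohort produces finite, reproducible, coupled signals", {
  sp <- cohort_spec(subjects_per_group = 3, channels = 4, duration = 2,
                    seed = 9)
  co <- synth_cohort(sp)
  expect_length(co, 6L)
  expect_equal(as.integer(table(vapply(co, `[[`, character(1), "group"))),
               c(3L, 3L))
  for (su in co) {
    expect_s3_class(su$signals, "signal_set")
    expect_equal(dim(su$signals$data), c(4L, 512L))
    expect_true(all(is.finite(su$signals$data)))
  }
  # seed determinism, including subject-in-isolation reproducibility
  co2 <- synth_cohort(sp)
  expect_identical(co[[5]]$signals$data, co2[[5]]$signals$data)

  # parameter validation
  expect_error(cohort_spec(channels = 4, coupling_A = matrix(1, 3, 3)),
               "4 x 4")
  bad <- matrix(0, 4, 4); bad[1, 2] <- -1
  expect_error(cohort_spec(channels = 4, coupling_A = bad), "nonnegative")
})

test_that("cohort coupling direction is recovered by the TE pipeline", {
  WA <- matrix(0, 4, 4); WA[1, 2] <- 0.6
  WB <- matrix(0, 4, 4)
  sp <- cohort_spec(subjects_per_group = 20, channels = 4, duration = 4,
                    coupling_A = WA, coupling_B = WB, seed = 21)
  co <- synth_cohort(sp)
  grp <- vapply(co, `[[`, character(1), "group")
  te12 <- vapply(co, function(su)
    te_matrix(su$signals)$weights[1, 2], numeric(1))
  expect_gt(mean(te12[grp == "A"]), mean(te12[grp == "B"]))
})

test_that("cohorts round-trip through the delimited container + manifest", {
  sp <- cohort_spec(subjects_per_group = 2, channels = 3, duration = 1,
                    seed = 4)
  co <- synth_cohort(sp)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back, 4L)
  expect_equal(back[[2]]$id, co[[2]]$id)
  expect_equal(back[[2]]$group, co[[2]]$group)
  expect_equal(back[[2]]$signals$data, co[[2]]$signals$data,
               tolerance = 1e-12, ignore_attr = TRUE)
})
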