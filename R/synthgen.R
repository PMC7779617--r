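#' Random graph with a prescribed node and edge count
#'
#' Draws exactly `n_edges` distinct node pairs uniformly without replacement:
#' ordered pairs (i, j), i != j, for a directed graph; unordered pairs for an
#' undirected one. Generation is deterministic given `seed`.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges; at most `n(n-1)` directed or `n(n-1)/2`
#'   undirected.
#' @param directed Logical; build a digraph (default) or undirected graph.
#' @param seed Integer seed.
#' @return A `binary_digraph`.
#' @examples
#' g <- random_graph(200, 787, seed = 1)
#' mean(colSums(g$adjacency))   # average in-degree 3.935
#' @export
random_graph <- function(n_nodes, n_edges, directed = TRUE, seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 1)
  n_edges <- check_count(n_edges, "n_edges", min = 0)
  max_edges <- if (directed) n_nodes * (n_nodes - 1L) else
    n_nodes * (n_nodes - 1L) / 2L
  if (n_edges > max_edges) {
    stop(sprintf("n_edges = %d exceeds the maximum %d for %d nodes",
                 n_edges, max_edges, n_nodes), call. = FALSE)
  }
  adj <- matrix(FALSE, n_nodes, n_nodes)
  # Enumerate candidate pairs once and sample their indices, so the draw is
  # uniform over edge sets and exactly reproducible.
  if (directed) {
    cand <- which(diag(n_nodes) == 0)
  } else {
    cand <- which(upper.tri(matrix(0, n_nodes, n_nodes)))
  }
  pick <- with_seed(seed, sample(cand, n_edges, replace = FALSE))
  adj[pick] <- TRUE
  if (!directed) adj <- adj | t(adj)
  binary_digraph(adj, directed = directed)
}

#' Noisy binary copy pair with known transfer entropy
#'
#' Generates `x` as an i.i.d. fair Bernoulli sequence and `y` as a one-step
#' lagged copy: `y[t + 1] = x[t]`, inverted with probability `flip_prob`
#' (`y[1]` is an independent fair coin). With history lengths and lags all
#' equal to one, the true transfer entropy from x to y is
#' `1 - H_b(flip_prob)` bits, where `H_b` is the binary entropy function, so
#' the pair is an estimator-validation fixture with a closed-form target.
#'
#' @param length Number of samples (>= 2).
#' @param flip_prob Probability in \[0, 1\] of inverting the copied bit.
#' @param seed Integer seed.
#' @return List with numeric 0/1 vectors `x` and `y` and the closed-form
#'   `te_true` in bits.
#' @export
noisy_copy_pair <- function(length, flip_prob, seed = 1L) {
  length <- check_count(length, "length", min = 2)
  if (!is.numeric(flip_prob) || length(flip_prob) != 1L ||
      is.na(flip_prob) || flip_prob < 0 || flip_prob > 1) {
    stop("`flip_prob` must be a probability in [0, 1]", call. = FALSE)
  }
  draws <- with_seed(seed, {
    x <- rbinom(length, 1L, 0.5)
    y0 <- rbinom(1L, 1L, 0.5)
    flips <- rbinom(length - 1L, 1L, flip_prob)
    list(x = x, y0 = y0, flips = flips)
  })
  y <- c(draws$y0, bitwXor(draws$x[-length], draws$flips))
  hb <- binary_entropy(flip_prob)
  list(x = as.numeric(draws$x), y = as.numeric(y), te_true = 1 - hb)
}

#' Binary entropy in bits
#'
#' @param p Probability (vectorised).
#' @return `-p log2 p - (1-p) log2 (1-p)`, with `0 log 0 = 0`.
#' @export
binary_entropy <- function(p) {
  term <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Specification for a two-cohort synthetic EEG-like dataset
#'
#' Each subject's channels follow a stable AR(2) process plus lag-1
#' cross-channel coupling and Gaussian innovation noise:
#' `s_j[t] = a1 s_j[t-1] + a2 s_j[t-2] + sum_i W[i, j] s_i[t-1] + e_j[t]`.
#' The two groups differ only through their coupling matrices, which is the
#' statistical structure the directed-connectivity pipeline must recover.
#'
#' @param subjects_per_group Subjects in each of the two groups.
#' @param channels Number of channels (default 16).
#' @param fs Sampling rate, Hz (default 256).
#' @param duration Segment length in seconds (default 20).
#' @param coupling_A,coupling_B `channels x channels` nonnegative coupling
#'   matrices (zero diagonal); entry (i, j) drives channel i into channel j
#'   at lag 1. Defaults are band-diagonal rings with reversed direction, so
#'   the groups differ in topology but not density.
#' @param noise_sd Innovation standard deviation.
#' @param ar Length-2 AR coefficient vector shared by all channels.
#' @param seed Integer base seed; subject k uses a counter-derived child
#'   seed so it is reproducible in isolation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(subjects_per_group = 50, channels = 16, fs = 256,
                        duration = 20, coupling_A = NULL, coupling_B = NULL,
                        noise_sd = 1, ar = c(0.5, -0.2), seed = 1L) {
  subjects_per_group <- check_count(subjects_per_group, "subjects_per_group",
                                    min = 1)
  channels <- check_count(channels, "channels", min = 2)
  if (is.null(coupling_A)) coupling_A <- ring_coupling(channels, 0.4)
  if (is.null(coupling_B)) coupling_B <- hub_coupling(channels, 0.4)
  for (nm in c("coupling_A", "coupling_B")) {
    W <- get(nm)
    if (!is.matrix(W) || nrow(W) != channels || ncol(W) != channels) {
      stop(sprintf("`%s` must be a %d x %d matrix", nm, channels, channels),
           call. = FALSE)
    }
    if (any(W < 0)) stop(sprintf("`%s` must be nonnegative", nm),
                         call. = FALSE)
    if (any(diag(W) != 0)) stop(sprintf("`%s` must have a zero diagonal", nm),
                                call. = FALSE)
  }
  structure(list(subjects_per_group = subjects_per_group,
                 channels = channels, fs = fs, duration = duration,
                 coupling_A = coupling_A, coupling_B = coupling_B,
                 noise_sd = noise_sd, ar = ar, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Directed coupling topologies for cohort defaults
#'
#' `ring_coupling` makes each channel drive its clockwise
#' (`direction = +1`) or counter-clockwise (`direction = -1`) neighbour;
#' `hub_coupling` makes channel 1 drive every other channel. The two
#' default cohort groups use a ring and a hub because the pipeline's
#' features are graph invariants: topologies that are merely re-oriented
#' or relabelled versions of each other (e.g. the two ring directions) are
#' isomorphic and produce identical attack curves.
#'
#' @param channels Number of channels.
#' @param strength Coupling strength.
#' @param direction `+1` or `-1`.
#' @return A `channels x channels` coupling matrix.
#' @export
ring_coupling <- function(channels, strength = 0.4, direction = 1L) {
  W <- matrix(0, channels, channels)
  for (i in seq_len(channels)) {
    j <- ((i - 1L + direction) %% channels) + 1L
    W[i, j] <- strength
  }
  W
}

#' @rdname ring_coupling
#' @export
hub_coupling <- function(channels, strength = 0.4) {
  W <- matrix(0, channels, channels)
  W[1L, 2:channels] <- strength
  W
}

#' Simulate a two-cohort collection of signal sets
#'
#' @param spec A `cohort_spec`.
#' @return An object of class `cohort`: a list of subjects, each a list with
#'   `id`, `group` ("A" or "B") and `signals` (a `signal_set`), plus the
#'   spec as an attribute.
#' @export
synth_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec",
                                           call. = FALSE)
  n_samp <- floor(spec$fs * spec$duration)
  subjects <- vector("list", 2L * spec$subjects_per_group)
  k <- 0L
  for (grp in c("A", "B")) {
    W <- if (grp == "A") spec$coupling_A else spec$coupling_B
    for (s in seq_len(spec$subjects_per_group)) {
      k <- k + 1L
      sig <- simulate_coupled_ar(W, n_samp, spec$noise_sd, spec$ar,
                                 child_seed(spec$seed, k))
      subjects[[k]] <- list(
        id = sprintf("%s%02d", grp, s), group = grp,
        signals = signal_set(sig, fs = spec$fs))
    }
  }
  structure(subjects, class = "cohort", spec = spec)
}

#' @export
print.cohort <- function(x, ...) {
  s1 <- x[[1L]]$signals
  cat(sprintf("<cohort> %d subjects, %d channels x %d samples @ %g Hz\n",
              length(x), n_channels(s1), n_samples(s1), s1$fs))
  invisible(x)
}

simulate_coupled_ar <- function(W, n_samp, noise_sd, ar, seed) {
  n_ch <- nrow(W)
  burn <- 200L
  total <- n_samp + burn
  eps <- with_seed(seed, matrix(rnorm(n_ch * total, sd = noise_sd),
                                n_ch, total))
  s <- matrix(0, n_ch, total)
  s[, 1L] <- eps[, 1L]
  s[, 2L] <- ar[1L] * s[, 1L] + crossprod(W, s[, 1L]) + eps[, 2L]
  for (t in 3:total) {
    s[, t] <- ar[1L] * s[, t - 1L] + ar[2L] * s[, t - 2L] +
      crossprod(W, s[, t - 1L]) + eps[, t]
  }
  out <- s[, (burn + 1L):total, drop = FALSE]
  if (any(!is.finite(out))) {
    stop("coupled AR simulation diverged; reduce coupling or AR coefficients",
         call. = FALSE)
  }
  out
}

#' Write a cohort to disk as delimited files plus a manifest
#'
#' Each subject becomes `<id>.csv` (samples in rows, channels in columns)
#' and `manifest.csv` records subject id, group, sampling rate and channel
#' names.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(su) {
    f <- file.path(dir, paste0(su$id, ".csv"))
    utils::write.csv(t(su$signals$data), f, row.names = FALSE)
    data.frame(id = su$id, group = su$group, fs = su$signals$fs,
               channels = paste(su$signals$channel_names, collapse = ";"),
               file = basename(f), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    dat <- t(as.matrix(utils::read.csv(file.path(dir, m$file))))
    list(id = m$id, group = m$group,
         signals = signal_set(dat, fs = m$fs,
                              channel_names = strsplit(m$channels, ";")[[1L]]))
  })
  structure(subjects, class = "cohort")
}
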