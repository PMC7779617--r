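#' Transfer-entropy estimator parameters
#'
#' Embedding and discretisation settings for the plug-in histogram
#' estimator: `d` is the history length of the target series, `m` of the
#' source, `tau` the embedding delay in samples, `u` the prediction horizon
#' in samples, and `n_bins` the number of equal-width amplitude bins per
#' dimension. The defaults (d = m = tau = u = 1, 8 bins) are the
#' lowest-order embedding, which keeps the joint histogram well populated
#' on 20-s segments.
#'
#' @param d,m,tau,u Positive integers.
#' @param n_bins Integer >= 2.
#' @return An object of class `te_params`.
#' @export
te_params <- function(d = 1L, m = 1L, tau = 1L, u = 1L, n_bins = 8L) {
  p <- list(d = check_count(d, "d", 1), m = check_count(m, "m", 1),
            tau = check_count(tau, "tau", 1), u = check_count(u, "u", 1),
            n_bins = check_count(n_bins, "n_bins", 2))
  structure(p, class = "te_params")
}

# Equal-width discretisation over the observed range. A constant series
# collapses to a single bin (so it carries no information and TE is 0).
discretize_series <- function(x, n_bins) {
  r <- range(x)
  if (r[1L] == r[2L]) return(rep(1L, length(x)))
  idx <- floor((x - r[1L]) / (r[2L] - r[1L]) * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

# Joint integer code of an embedded state: rows of `mat` are time points,
# columns the embedding coordinates, each in 1..n_bins.
joint_code <- function(mat, n_bins) {
  code <- rep(0, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    code <- code * n_bins + (mat[, j] - 1L)
  }
  code
}

entropy_from_codes <- function(code) {
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Transfer entropy between two series (plug-in histogram estimate)
#'
#' Estimates the information (in bits) that the past of `y` adds about the
#' future of `x` beyond x's own past. Both series are discretised into
#' `n_bins` equal-width bins; the delay-embedded states `X_t^d` (target
#' past), `Y_t^m` (source past) and the future sample `x_{t+u}` form a
#' joint histogram, and the transfer entropy is evaluated as the
#' four-entropy combination
#' `H(X^d, Y^m) - H(x_+, X^d, Y^m) + H(x_+, X^d) - H(X^d)`,
#' which is algebraically identical to the direct conditional-probability
#' summation over the joint cells (zero-probability cells contribute
#' nothing). Small negative estimates, impossible analytically but possible
#' numerically, are clipped to 0; the unclipped value is kept in the
#' `"raw"` attribute.
#'
#' @param x Target numeric series.
#' @param y Source numeric series, same length.
#' @param p A `te_params`.
#' @return Transfer entropy from y to x in bits (>= 0).
#' @examples
#' pair <- noisy_copy_pair(20000, flip_prob = 0, seed = 1)
#' transfer_entropy(pair$y, pair$x, te_params(n_bins = 2))  # ~1 bit
#' @export
transfer_entropy <- function(x, y, p = te_params()) {
  if (!inherits(p, "te_params")) stop("`p` must be te_params", call. = FALSE)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  n <- length(x)
  t_min <- 1L + (max(p$d, p$m) - 1L) * p$tau
  t_max <- n - p$u
  if (t_max < t_min) {
    stop(sprintf(
      "series too short: need length >= %d for d=%d, m=%d, tau=%d, u=%d",
      p$u + (max(p$d, p$m) - 1L) * p$tau + 1L, p$d, p$m, p$tau, p$u),
      call. = FALSE)
  }
  xb <- discretize_series(x, p$n_bins)
  yb <- discretize_series(y, p$n_bins)
  te_from_codes(xb, yb, p)
}

# Core estimator on pre-discretised series; reused by te_matrix so each
# channel is binned exactly once.
te_from_codes <- function(xb, yb, p) {
  n <- length(xb)
  t_idx <- (1L + (max(p$d, p$m) - 1L) * p$tau):(n - p$u)
  xfut <- xb[t_idx + p$u]
  xpast <- sapply(0:(p$d - 1L), function(l) xb[t_idx - l * p$tau])
  ypast <- sapply(0:(p$m - 1L), function(l) yb[t_idx - l * p$tau])
  if (!is.matrix(xpast)) xpast <- matrix(xpast, ncol = p$d)
  if (!is.matrix(ypast)) ypast <- matrix(ypast, ncol = p$m)
  cx <- joint_code(xpast, p$n_bins)
  cy <- joint_code(ypast, p$n_bins)
  nb <- as.double(p$n_bins)
  span_y <- nb^p$m
  c_xy <- cx * span_y + cy
  c_fxy <- (xfut - 1L) * nb^p$d * span_y + c_xy
  c_fx <- (xfut - 1L) * nb^p$d + cx
  te <- entropy_from_codes(c_xy) - entropy_from_codes(c_fxy) +
    entropy_from_codes(c_fx) - entropy_from_codes(cx)
  structure(max(te, 0), raw = te)
}

#' Transfer entropy from an exact joint distribution
#'
#' Evaluates the transfer-entropy functional on a known joint probability
#' array of `(x_future, X_past_state, Y_past_state)` instead of on data.
#' Two algebraically equivalent routes are provided: `"direct"` sums
#' `p log2( p(x_+ | X, Y) / p(x_+ | X) )` over the joint cells, and
#' `"entropies"` combines the four marginal Shannon entropies. Their
#' agreement (to numerical precision) on arbitrary joints is a correctness
#' invariant of the functional.
#'
#' @param joint 3-dimensional numeric array of nonnegative cell
#'   probabilities summing to 1; dimension 1 indexes the future target
#'   state, dimension 2 the target-past state, dimension 3 the source-past
#'   state.
#' @param method `"direct"` or `"entropies"`.
#' @return Transfer entropy in bits.
#' @examples
#' # two independent fair coins: factorized joint, TE exactly 0
#' te_from_joint(array(1 / 8, c(2, 2, 2)))
#' @export
te_from_joint <- function(joint, method = c("direct", "entropies")) {
  method <- match.arg(method)
  if (!is.array(joint) || length(dim(joint)) != 3L) {
    stop("`joint` must be a 3-dimensional array", call. = FALSE)
  }
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-9) {
    stop("`joint` must be a probability array (nonnegative, sums to 1)",
         call. = FALSE)
  }
  p_xy <- apply(joint, c(2, 3), sum)      # p(X, Y)
  p_fx <- apply(joint, c(1, 2), sum)      # p(x_+, X)
  p_x <- apply(joint, 2, sum)             # p(X)
  if (method == "entropies") {
    hh <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    return(hh(p_xy) - hh(joint) + hh(p_fx) - hh(p_x))
  }
  te <- 0
  dm <- dim(joint)
  for (f in seq_len(dm[1L])) for (i in seq_len(dm[2L])) {
    for (j in seq_len(dm[3L])) {
      pc <- joint[f, i, j]
      if (pc <= 0) next
      cond_xy <- pc / p_xy[i, j]
      cond_x <- p_fx[f, i] / p_x[i]
      te <- te + pc * log2(cond_xy / cond_x)
    }
  }
  te
}

#' Transfer-entropy matrix over all ordered channel pairs
#'
#' Entry (i, j) of the result is the transfer entropy from channel i to
#' channel j, i.e. channel j is the target whose future is predicted.
#' The matrix is asymmetric in general; the two directions of each pair
#' are independent computations and are never symmetrised.
#'
#' @param s A `signal_set` with at least 2 channels.
#' @param p A `te_params`.
#' @return A `weighted_digraph` with the channel names as node labels.
#' @export
te_matrix <- function(s, p = te_params()) {
  if (!inherits(s, "signal_set")) stop("`s` must be a signal_set",
                                       call. = FALSE)
  n <- n_channels(s)
  if (n < 2L) stop("need at least 2 channels", call. = FALSE)
  codes <- lapply(seq_len(n), function(i)
    discretize_series(s$data[i, ], p$n_bins))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    W[i, j] <- tryCatch(
      as.numeric(te_from_codes(codes[[j]], codes[[i]], p)),
      error = function(e) stop(sprintf("pair (%s -> %s): %s",
                                       s$channel_names[i],
                                       s$channel_names[j],
                                       conditionMessage(e)), call. = FALSE))
  }
  weighted_digraph(W, node_labels = s$channel_names)
}

#' Per-rhythm connectivity for one subject
#'
#' Applies [te_matrix()] to each band of a `rhythm_set`, giving four
#' weighted directed networks on the same node ordering. When the subject's
#' recording was segmented, pass `segments` as a list of `rhythm_set`s and
#' the per-segment matrices are combined according to `aggregate`:
#' `"mean"` averages the TE weight matrices across segments (the default),
#' `"concat"` concatenates segments in time before estimating.
#'
#' @param rs A `rhythm_set`, or a list of `rhythm_set`s (one per segment).
#' @param p A `te_params`.
#' @param aggregate `"mean"` or `"concat"`; used only for segment lists.
#' @return Named list of four `weighted_digraph`s (beta, alpha, theta,
#'   delta).
#' @export
subject_connectivity <- function(rs, p = te_params(),
                                 aggregate = c("mean", "concat")) {
  aggregate <- match.arg(aggregate)
  if (inherits(rs, "rhythm_set")) rs <- list(rs)
  if (!length(rs) || !all(vapply(rs, inherits, logical(1), "rhythm_set"))) {
    stop("`rs` must be a rhythm_set or a non-empty list of rhythm_sets",
         call. = FALSE)
  }
  bands <- names(rhythm_bands())
  out <- lapply(bands, function(b) {
    if (length(rs) == 1L) return(te_matrix(rs[[1L]][[b]], p))
    if (aggregate == "concat") {
      dat <- do.call(cbind, lapply(rs, function(seg) seg[[b]]$data))
      return(te_matrix(signal_set(dat, rs[[1L]][[b]]$fs,
                                  rs[[1L]][[b]]$channel_names), p))
    }
    mats <- lapply(rs, function(seg) te_matrix(seg[[b]], p)$weights)
    weighted_digraph(Reduce(`+`, mats) / length(mats),
                     node_labels = rs[[1L]][[b]]$channel_names)
  })
  names(out) <- bands
  out
}
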