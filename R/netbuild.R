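#' Fixed-step threshold grid
#'
#' Equally spaced binarization thresholds over the half-open interval
#' `(start, stop]`: `start + step, start + 2 step, ..., stop`. The defaults
#' sweep (0, 0.006] in steps of 1e-5, i.e. 600 thresholds.
#'
#' @param start Lower bound (exclusive).
#' @param stop Upper bound (inclusive).
#' @param step Positive increment; must be commensurate with the range.
#' @return Numeric vector of thresholds of length
#'   `round((stop - start) / step)`.
#' @examples
#' length(threshold_grid())   # 600
#' @export
threshold_grid <- function(start = 0, stop = 0.006, step = 1e-5) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a single positive number", call. = FALSE)
  }
  if (stop <= start) stop("`stop` must exceed `start`", call. = FALSE)
  count <- round((stop - start) / step)
  start + step * seq_len(count)
}

#' Binarize a weighted digraph at a threshold
#'
#' Edge (i, j) is present in the result iff `weights(i, j) > t` (strict, so
#' t = 0 already excludes zero-weight pairs). The diagonal stays empty.
#'
#' @param w A `weighted_digraph`.
#' @param t Threshold (>= 0).
#' @return A `binary_digraph` on the same nodes.
#' @export
binarize <- function(w, t) {
  if (!inherits(w, "weighted_digraph")) {
    stop("`w` must be a weighted_digraph", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("`t` must be a single nonnegative threshold", call. = FALSE)
  }
  binary_digraph(w$weights > t, node_labels = w$node_labels)
}

#' Group-level sample network by right-tailed t-test
#'
#' Descriptive group network: for each ordered node pair, the subjects'
#' edge weights form a sample, and the edge is drawn iff the one-sample
#' right-tailed t-test rejects the null that the sample mean is `t` (in
#' favour of being greater) at level `alpha`. A zero-variance sample has an
#' undefined t statistic; the edge is then decided by the sign of
#' `mean - t` (present iff strictly positive).
#'
#' @param weight_list List of `weighted_digraph`s (one per subject, same
#'   nodes in the same order), or a 3-d array `n x n x subjects`.
#' @param t Threshold tested against.
#' @param alpha Significance level (default 0.01).
#' @return A `binary_digraph`.
#' @export
group_sample_network <- function(weight_list, t, alpha = 0.01) {
  if (is.list(weight_list)) {
    mats <- lapply(weight_list, function(w) {
      if (!inherits(w, "weighted_digraph")) {
        stop("`weight_list` entries must be weighted_digraphs", call. = FALSE)
      }
      w$weights
    })
    labels <- weight_list[[1L]]$node_labels
    arr <- array(unlist(mats), dim = c(dim(mats[[1L]]), length(mats)))
  } else if (is.array(weight_list) && length(dim(weight_list)) == 3L) {
    arr <- weight_list
    labels <- paste0("v", seq_len(dim(arr)[1L]))
  } else {
    stop("`weight_list` must be a list of weighted_digraphs or an n x n x s array",
         call. = FALSE)
  }
  ns <- dim(arr)[3L]
  if (ns < 2L) stop("need at least 2 subjects for the t-test", call. = FALSE)
  n <- dim(arr)[1L]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sample <- arr[i, j, ]
    sdv <- stats::sd(sample)
    if (sdv == 0) {
      adj[i, j] <- mean(sample) > t
    } else {
      stat <- (mean(sample) - t) / (sdv / sqrt(ns))
      pval <- stats::pt(stat, df = ns - 1L, lower.tail = FALSE)
      adj[i, j] <- pval < alpha
    }
  }
  binary_digraph(adj, node_labels = labels)
}
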