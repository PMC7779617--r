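#' Mode-k matricization (unfolding) of a tensor
#'
#' Arranges the mode-k fibers of an array as columns of a matrix, with the
#' remaining modes cycling in increasing order (the standard convention for
#' Tucker algebra).
#'
#' @param a Numeric array.
#' @param k Mode along which to unfold.
#' @return Matrix with `dim(a)[k]` rows.
#' @export
unfold <- function(a, k) {
  d <- dim(a)
  perm <- c(k, setdiff(seq_along(d), k))
  matrix(aperm(a, perm), nrow = d[k])
}

#' @rdname unfold
#' @param m Matrix produced by `unfold`.
#' @param dims Dimensions of the original tensor.
#' @return `fold` returns the array with dimensions `dims`.
#' @export
fold <- function(m, k, dims) {
  perm <- c(k, setdiff(seq_along(dims), k))
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Mode-k tensor-matrix product
#'
#' Multiplies matrix `mat` into mode `k` of tensor `a`
#' (each mode-k fiber is replaced by `mat` times that fiber).
#'
#' @param a Numeric array.
#' @param mat Matrix with `ncol(mat) == dim(a)[k]`.
#' @param k Mode.
#' @return Array with mode-k dimension `nrow(mat)`.
#' @export
ttm <- function(a, mat, k) {
  d <- dim(a)
  if (ncol(mat) != d[k]) stop("dimension mismatch in mode-k product",
                              call. = FALSE)
  fold(mat %*% unfold(a, k), k, replace(d, k, nrow(mat)))
}

frobenius <- function(a) sqrt(sum(a^2))

#' Build the five-way feature tensor for one subject
#'
#' For each rhythm network, each threshold in the grid, each edge-removal
#' sub-approach and each removal step, the residual network's average
#' clustering coefficient and network efficiency are recorded. The result
#' is indexed `(threshold, removal step, sub-approach, feature, rhythm)`
#' with sub-approaches ordered (receive, send), features (clustering
#' coefficient, efficiency) and rhythms (beta, alpha, theta, delta); with
#' h thresholds and n nodes the shape is h x n x 2 x 2 x 4. Removal step j
#' holds the j-th residual network (the un-attacked network is step 0 of
#' [feature_curves()] and is not a tensor slab). All entries lie in
#' \[0, 1\].
#'
#' @param conn Named list of four `weighted_digraph`s as returned by
#'   [subject_connectivity()].
#' @param grid Numeric threshold vector from [threshold_grid()].
#' @return 5-d numeric array of class `feature_tensor` with informative
#'   dimnames.
#' @export
build_feature_tensor <- function(conn, grid) {
  bands <- names(rhythm_bands())
  if (!all(bands %in% names(conn))) {
    stop("`conn` must contain all four rhythms: ",
         paste(bands, collapse = ", "), call. = FALSE)
  }
  ns <- vapply(conn[bands], function(w) length(w$node_labels), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all rhythm networks must share the node count", call. = FALSE)
  }
  n <- ns[[1L]]
  h <- length(grid)
  modes <- c("receive", "send")
  feats <- c("C", "N")
  q <- array(NA_real_, dim = c(h, n, 2L, 2L, 4L),
             dimnames = list(threshold = signif(grid, 8),
                             step = seq_len(n), mode = modes,
                             feature = feats, rhythm = bands))
  for (r in seq_along(bands)) {
    w <- conn[[bands[r]]]
    for (i in seq_len(h)) {
      g <- binarize(w, grid[i])
      for (a in seq_along(modes)) {
        seq_a <- edge_removal_sequence(g, modes[a])
        for (j in seq_len(n)) {
          res <- seq_a$residuals[[j]]
          q[i, j, a, 1L, r] <- avg_clustering(res)
          q[i, j, a, 2L, r] <- efficiency(res)
        }
      }
    }
  }
  class(q) <- c("feature_tensor", class(q))
  q
}

#' Candidate Tucker core shapes for the complete-trial search
#'
#' Core dimensions are kept strictly between 1 and 10: the sub-approach and
#' feature modes stay at 2, the rhythm mode ranges over 2, 3, 4, and the
#' threshold and removal-step modes range over `2 ... min(dim, 9)`. The
#' number of candidates is therefore
#' `3 * min(h - 1, 8) * min(n - 1, 8)`.
#'
#' @param h Number of thresholds (>= 2).
#' @param n Number of nodes / removal steps (>= 2).
#' @return List of integer shape vectors `c(l1, l2, 2, 2, l5)`.
#' @examples
#' length(core_shape_grid(600, 16))   # 192
#' @export
core_shape_grid <- function(h, n) {
  h <- check_count(h, "h", 2)
  n <- check_count(n, "n", 2)
  l1s <- 2:min(h, 9L)
  l2s <- 2:min(n, 9L)
  l5s <- 2:4
  out <- list()
  for (l1 in l1s) for (l2 in l2s) for (l5 in l5s) {
    out[[length(out) + 1L]] <- c(l1, l2, 2L, 2L, l5)
  }
  out
}

# Leading r left singular vectors; pads with an orthonormal complement in
# the (rare) case r exceeds the matrix rank bound min(nrow, ncol).
left_svecs <- function(x, r) {
  u <- svd(x, nu = min(nrow(x), ncol(x)), nv = 0)$u
  if (ncol(u) >= r) return(u[, seq_len(r), drop = FALSE])
  qr.Q(qr(cbind(u, diag(nrow(x)))))[, seq_len(r), drop = FALSE]
}

hosvd_factors <- function(q, core_shape) {
  lapply(seq_along(core_shape), function(k) {
    left_svecs(unfold(q, k), core_shape[k])
  })
}

#' Tucker decomposition by higher-order orthogonal iteration
#'
#' Decomposes tensor `q` into a small core and per-mode column-orthonormal
#' factor matrices, `q ~ core x_1 U1 x_2 U2 ... x_K UK`. The factors are
#' initialised by truncated higher-order SVD and refined by alternating
#' orthogonal iteration (each sweep updates one factor to the leading left
#' singular vectors of the partially projected tensor). The fit fraction
#' `psi = 1 - ||q - qhat||^2 / ||q||^2` is non-decreasing over sweeps;
#' iteration stops when it improves by less than `tol` or after `max_iter`
#' sweeps.
#'
#' @param q Numeric array.
#' @param core_shape Integer vector, one target rank per mode, each between
#'   1 and the mode's dimension.
#' @param max_iter Maximum number of sweeps (default 50).
#' @param tol Convergence tolerance on the fit improvement (default 1e-6).
#' @return An object of class `tucker_result`: list with `core`, `factors`,
#'   `fit` (psi), `iterations`, and the original dimensions.
#' @export
tucker_hooi <- function(q, core_shape, max_iter = 50L, tol = 1e-6) {
  d <- dim(q)
  if (length(core_shape) != length(d)) {
    stop("`core_shape` must give one rank per tensor mode", call. = FALSE)
  }
  core_shape <- vapply(core_shape, check_count, integer(1),
                       name = "core_shape", min = 1)
  if (any(core_shape > d)) {
    stop("`core_shape` must not exceed the tensor dimensions", call. = FALSE)
  }
  nrm2 <- sum(q^2)
  if (nrm2 == 0) {
    # degenerate all-zero tensor: any orthonormal factors represent it
    factors <- lapply(seq_along(d), function(k)
      diag(d[k])[, seq_len(core_shape[k]), drop = FALSE])
    core <- array(0, core_shape)
    return(structure(list(core = core, factors = factors, fit = 1,
                          iterations = 0L, dims = d),
                     class = "tucker_result"))
  }
  factors <- hosvd_factors(q, core_shape)
  fit <- core_norm2(q, factors) / nrm2
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (k in seq_along(d)) {
      y <- q
      for (j in seq_along(d)) {
        if (j != k) y <- ttm(y, t(factors[[j]]), j)
      }
      factors[[k]] <- left_svecs(unfold(y, k), core_shape[k])
    }
    fit_new <- core_norm2(q, factors) / nrm2
    if (fit_new - fit < tol) { fit <- fit_new; break }
    fit <- fit_new
  }
  core <- q
  for (k in seq_along(d)) core <- ttm(core, t(factors[[k]]), k)
  structure(list(core = core, factors = factors, fit = fit,
                 iterations = iter, dims = d),
            class = "tucker_result")
}

core_norm2 <- function(q, factors) {
  core <- q
  for (k in seq_along(factors)) core <- ttm(core, t(factors[[k]]), k)
  sum(core^2)
}

#' @export
print.tucker_result <- function(x, ...) {
  cat(sprintf("<tucker_result> core %s from tensor %s; psi = %.6f (%d iter)\n",
              paste(dim(x$core), collapse = "x"),
              paste(x$dims, collapse = "x"), x$fit, x$iterations))
  invisible(x)
}

#' Reconstruct the approximation from a Tucker result
#'
#' @param result A `tucker_result`.
#' @return Array of the original dimensions.
#' @export
tucker_reconstruct <- function(result) {
  a <- result$core
  for (k in seq_along(result$factors)) a <- ttm(a, result$factors[[k]], k)
  a
}

#' Fraction of the tensor explained by a Tucker decomposition
#'
#' The default (`method = "fit"`) is the standard Tucker fit fraction
#' `1 - ||Q - Qhat||^2 / ||Q||^2`. `method = "ratio"` evaluates the
#' alternative form `1 - (||Q||^2 - ||core||^2) / ||Q||`, which mixes
#' squared and unsquared norms; it coincides with the default at a perfect
#' fit and is kept for auditability only. A zero-norm tensor is defined as
#' fully explained (psi = 1).
#'
#' @param q The original tensor.
#' @param result A `tucker_result` for `q`.
#' @param method `"fit"` (default) or `"ratio"`.
#' @return The explained fraction psi.
#' @export
fraction_explained <- function(q, result, method = c("fit", "ratio")) {
  method <- match.arg(method)
  nq <- frobenius(q)
  if (nq == 0) return(1)
  if (method == "ratio") {
    return(1 - (nq^2 - frobenius(result$core)^2) / nq)
  }
  1 - frobenius(q - tucker_reconstruct(result))^2 / nq^2
}

#' Flatten a Tucker core into a classifier feature vector
#'
#' The core is vectorised with the first mode (threshold) varying slowest
#' and the last mode (rhythm) fastest, so cores of equal shape map to
#' comparable coordinates across subjects. `unreshape_core` inverts the
#' flattening.
#'
#' @param result A `tucker_result`, or a bare core array.
#' @return Numeric vector of length `prod(core shape)`.
#' @export
reshape_core <- function(result) {
  core <- if (inherits(result, "tucker_result")) result$core else result
  as.vector(aperm(core, rev(seq_along(dim(core)))))
}

#' @rdname reshape_core
#' @param v Vector produced by `reshape_core`.
#' @param shape Core shape.
#' @return `unreshape_core` returns the core array.
#' @export
unreshape_core <- function(v, shape) {
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}
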