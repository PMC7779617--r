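#' Multichannel time-series container
#'
#' A `signal_set` holds a channels-by-samples numeric matrix together with
#' its sampling rate and channel names. It is the carrier for raw EEG-like
#' recordings and for every band-limited version produced downstream.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel. Defaults to
#'   `ch1 ... chk`.
#' @return An object of class `signal_set`.
#' @examples
#' s <- signal_set(matrix(rnorm(512), 2, 256), fs = 256)
#' print(s)
#' @export
signal_set <- function(data, fs, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)",
         call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("`data` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (ncol(data) < 2L) stop("need at least 2 samples per channel",
                            call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = as.character(channel_names)),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  invisible(x)
}

#' Number of channels / samples in a signal set
#' @param s A `signal_set`.
#' @return Integer count.
#' @export
n_channels <- function(s) nrow(s$data)

#' @rdname n_channels
#' @export
n_samples <- function(s) ncol(s$data)

#' Rhythm-band container
#'
#' A `rhythm_set` is a named list of four `signal_set`s, one per canonical
#' EEG band: beta (13--30 Hz), alpha (8--13 Hz), theta (4--8 Hz) and delta
#' (1--4 Hz). All four members share shape and sampling rate.
#'
#' @param beta,alpha,theta,delta `signal_set`s of identical shape and fs.
#' @return An object of class `rhythm_set`.
#' @export
rhythm_set <- function(beta, alpha, theta, delta) {
  bands <- list(beta = beta, alpha = alpha, theta = theta, delta = delta)
  for (nm in names(bands)) {
    if (!inherits(bands[[nm]], "signal_set")) {
      stop(sprintf("band '%s' must be a signal_set", nm), call. = FALSE)
    }
  }
  ref <- bands[[1L]]
  for (nm in names(bands)[-1L]) {
    b <- bands[[nm]]
    if (!identical(dim(b$data), dim(ref$data)) || b$fs != ref$fs) {
      stop("all four rhythm bands must share shape and sampling rate",
           call. = FALSE)
    }
  }
  structure(bands, class = "rhythm_set")
}

#' @export
print.rhythm_set <- function(x, ...) {
  cat(sprintf("<rhythm_set> bands %s; %d channels x %d samples @ %g Hz\n",
              paste(names(x), collapse = "/"),
              n_channels(x[[1L]]), n_samples(x[[1L]]), x[[1L]]$fs))
  invisible(x)
}

#' Canonical rhythm band edges (Hz)
#'
#' @return Named list of `c(low, high)` pairs for beta, alpha, theta, delta.
#' @export
rhythm_bands <- function() {
  list(beta = c(13, 30), alpha = c(8, 13), theta = c(4, 8), delta = c(1, 4))
}
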