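# Periodized orthogonal wavelet-packet transform with the Daubechies db4
# (8-tap) filter pair. Only what rhythm-band extraction needs: full
# decomposition to a given depth, frequency ordering of the terminal nodes,
# and reconstruction from a subset of terminal nodes.

# db4 orthonormal scaling filter (sums to sqrt(2)); the quadrature mirror
# highpass is derived by the alternating-sign rule.
DB4_H <- c(0.23037781330885523, 0.71484657055254150,
           0.63088076792959040, -0.02798376941698385,
           -0.18703481171888114, 0.03084138183598697,
           0.03288301166698294, -0.01059740178499728)
DB4_G <- (-1)^(0:7) * rev(DB4_H)

wpt_analysis_step <- function(x, h = DB4_H, g = DB4_G) {
  n <- length(x)
  half <- n %/% 2L
  idx <- (outer(2L * (0:(half - 1L)), 0:(length(h) - 1L), "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

wpt_synthesis_step <- function(a, d, h = DB4_H, g = DB4_G) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (0:(half - 1L))
  for (m in seq_along(h)) {
    pos <- ((base + (m - 1L)) %% n) + 1L
    x[pos] <- x[pos] + a * h[m] + d * g[m]
  }
  x
}

# Full wavelet-packet decomposition of one channel to `depth` levels.
# Returns the 2^depth terminal coefficient vectors in natural (filter-path)
# order. The signal length must be divisible by 2^depth.
wpt_decompose <- function(x, depth) {
  if (length(x) %% 2L^depth != 0L) {
    stop(sprintf("signal length %d must be divisible by 2^%d",
                 length(x), depth), call. = FALSE)
  }
  nodes <- list(x)
  for (lev in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      st <- wpt_analysis_step(nodes[[i]])
      nxt[[2L * i - 1L]] <- st$a
      nxt[[2L * i]] <- st$d
    }
    nodes <- nxt
  }
  nodes
}

# Reconstruct a channel from terminal coefficients, zeroing every node not
# in `keep` (indices in natural order).
wpt_reconstruct <- function(nodes, keep) {
  cur <- lapply(seq_along(nodes), function(i) {
    if (i %in% keep) nodes[[i]] else numeric(length(nodes[[i]]))
  })
  while (length(cur) > 1L) {
    nxt <- vector("list", length(cur) %/% 2L)
    for (i in seq_along(nxt)) {
      nxt[[i]] <- wpt_synthesis_step(cur[[2L * i - 1L]], cur[[2L * i]])
    }
    cur <- nxt
  }
  cur[[1L]]
}

# Frequency interval covered by each terminal node, in natural order.
# Downsampling a highpass branch mirrors the spectrum, so the low/high
# assignment flips along highpass paths; the recursion tracks that flip.
wpt_node_bands <- function(fs, depth) {
  rec <- function(f1, f2, flipped, level) {
    if (level == 0L) {
      return(data.frame(low = f1, high = f2))
    }
    mid <- (f1 + f2) / 2
    if (!flipped) {
      rbind(rec(f1, mid, FALSE, level - 1L),   # lowpass child
            rec(mid, f2, TRUE, level - 1L))    # highpass child
    } else {
      rbind(rec(mid, f2, TRUE, level - 1L),    # lowpass child (flipped)
            rec(f1, mid, FALSE, level - 1L))   # highpass child (flipped)
    }
  }
  bands <- rec(0, fs / 2, FALSE, depth)
  bands$node <- seq_len(nrow(bands))
  bands$center <- (bands$low + bands$high) / 2
  bands
}
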