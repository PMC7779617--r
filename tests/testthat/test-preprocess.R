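make_tone <- function(freq, fs, secs = 4, channels = 1) {
  tt <- (0:(fs * secs - 1)) / fs
  signal_set(matrix(rep(sin(2 * pi * freq * tt), channels),
                    nrow = channels, byrow = TRUE), fs)
}

band_power_fraction <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = FALSE)
  sum(sp$spec[sp$freq > lo & sp$freq <= hi]) / sum(sp$spec)
}

test_that("50 Hz notch suppresses mains and spares the passband", {
  s50 <- make_tone(50, 512, secs = 20)
  out <- notch_50hz(s50)
  expect_equal(dim(out$data), dim(s50$data))
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(s50$data^2)), 0.05)

  s10 <- make_tone(10, 512)
  out10 <- notch_50hz(s10)
  expect_equal(sqrt(mean(out10$data^2)) / sqrt(mean(s10$data^2)), 1,
               tolerance = 0.05)

  zero <- signal_set(matrix(0, 2, 1024), 512)
  expect_equal(notch_50hz(zero)$data, zero$data, ignore_attr = TRUE)

  expect_error(notch_50hz(signal_set(matrix(rnorm(200), 1), fs = 100)),
               "100 Hz")
})

test_that("resampling scales the sample count and anti-aliases", {
  s <- signal_set(matrix(rnorm(2 * 10240), 2), 512)
  r <- resample_signals(s, 256)
  expect_equal(n_samples(r), 5120L)
  expect_equal(r$fs, 256)
  expect_equal(r$channel_names, s$channel_names)

  expect_identical(resample_signals(s, 512), s)
  expect_error(resample_signals(s, 0), "positive")
  expect_error(resample_signals(s, 1024), "exceed")

  # a 100 Hz tone lies above the new 64 Hz Nyquist: its alias band must be
  # essentially empty after resampling to 128 Hz
  tone <- make_tone(100, 512, secs = 20)
  r2 <- resample_signals(tone, 128)
  expect_lt(band_power_fraction(r2$data[1, ], 128, 26, 30) *
              sum(r2$data[1, ]^2) / sum(tone$data[1, ]^2), 0.05)
})

test_that("segmentation drops the trailing partial window", {
  s <- signal_set(matrix(rnorm(2 * 256 * 120), 2), 256)
  expect_length(segment_signals(s, 20), 6L)
  s2 <- signal_set(matrix(rnorm(2 * 256 * 130), 2), 256)
  segs <- segment_signals(s2, 20)
  expect_length(segs, 6L)
  expect_true(all(vapply(segs, n_samples, integer(1)) == 20 * 256))
  # reassembling the segments reproduces the leading samples
  expect_equal(do.call(cbind, lapply(segs, function(x) x$data)),
               s2$data[, 1:(6 * 20 * 256)], ignore_attr = TRUE)
  s3 <- signal_set(matrix(rnorm(2 * 256 * 19), 2), 256)
  expect_warning(out <- segment_signals(s3, 20), "shorter")
  expect_length(out, 0L)
})

test_that("rhythm decomposition concentrates energy in the right band", {
  for (backend in c("butter", "wavelet")) {
    ra <- decompose_rhythms(make_tone(10, 256, 8), backend = backend)
    tot <- sum(vapply(ra, function(z) sum(z$data^2), numeric(1)))
    expect_gt(sum(ra$alpha$data^2) / tot, if (backend == "butter") 0.9 else 0.8)

    rd <- decompose_rhythms(make_tone(2, 256, 8), backend = backend)
    totd <- sum(vapply(rd, function(z) sum(z$data^2), numeric(1)))
    expect_gt(sum(rd$delta$data^2) / totd, 0.9)
  }

  zero <- signal_set(matrix(0, 2, 2560), 256)
  rz <- decompose_rhythms(zero)
  for (b in names(rz)) expect_equal(max(abs(rz[[b]]$data)), 0)

  expect_error(decompose_rhythms(signal_set(matrix(rnorm(100), 1), 32)),
               "64 Hz")
})

test_that("default backend keeps >=80% of band output power in-band on white noise", {
  set.seed(42)
  wn <- signal_set(matrix(rnorm(2 * 256 * 20), 2), 256)
  rs <- decompose_rhythms(wn)
  edges <- rhythm_bands()
  for (b in names(rs)) {
    frac <- band_power_fraction(rs[[b]]$data[1, ], 256,
                                edges[[b]][1], edges[[b]][2])
    expect_gt(frac, 0.8)
  }
  # summed band energies stay below total input energy (bands are subsets)
  tot_bands <- sum(vapply(rs, function(z) sum(z$data^2), numeric(1)))
  expect_lt(tot_bands, sum(wn$data^2) * 1.05)
})

test_that("wavelet packet transform is orthogonal and perfectly reconstructing", {
  set.seed(7)
  x <- rnorm(512)
  nodes <- epitensor:::wpt_decompose(x, 4)
  expect_equal(epitensor:::wpt_reconstruct(nodes, seq_along(nodes)), x,
               tolerance = 1e-9)
  expect_equal(sum(vapply(nodes, function(z) sum(z^2), numeric(1))),
               sum(x^2), tolerance = 1e-9)
  # frequency-ordered node table tiles [0, Nyquist] without gaps
  nb <- epitensor:::wpt_node_bands(256, 4)
  o <- order(nb$low)
  expect_equal(nb$low[o], seq(0, 120, by = 8))
  expect_equal(nb$high[o], seq(8, 128, by = 8))
  expect_error(epitensor:::wpt_decompose(rnorm(100), 6), "divisible")
})

test_that("preprocess_subject chains the stages and preserves channel identity", {
  tt <- (0:(512 * 41 - 1)) / 512
  raw <- signal_set(rbind(sin(2 * pi * 10 * tt) + 0.5 * sin(2 * pi * 50 * tt),
                          rnorm(length(tt))),
                    fs = 512, channel_names = c("Fp1", "Fp2"))
  prep <- preprocess_subject(raw, fs_out = 256, seg_seconds = 20)
  expect_length(prep$segments, 2L)
  expect_s3_class(prep$segments[[1]], "rhythm_set")
  expect_equal(prep$segments[[1]]$alpha$channel_names, c("Fp1", "Fp2"))
  expect_equal(prep$segments[[1]]$alpha$fs, 256)
  expect_true(any(grepl("skipped", prep$log)))
  expect_equal(prep$log[1], "notch_50hz")

  # artifact hook is applied when supplied
  marked <- preprocess_subject(raw, artifact_fun = function(s) {
    signal_set(s$data * 0.5, s$fs, s$channel_names)
  })
  expect_true(any(grepl("user hook", marked$log)))
})
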