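pink_record <- function(dur = 1200, fs = 200, seed = 11, rms = 10) {
  set.seed(seed)
  n <- dur * fs
  X <- stats::fft(stats::rnorm(n))
  f <- pmin((seq_len(n) - 1) * fs / n, fs - (seq_len(n) - 1) * fs / n)
  f[1] <- Inf
  x <- Re(stats::fft(X * f^-0.5, inverse = TRUE)) / n
  eeg_recording(list(ch = x / stats::sd(x) * rms), fs)
}

test_that("a scaled span is flagged and quiet spans are not", {
  rec <- pink_record()
  rec_bad <- inject_artifacts(rec, data.frame(start_s = 600,
                                              duration_s = 30, gain = 20))
  sp <- compute_spectrogram(rec_bad, "ch")
  mask <- detect_noise_epochs(sp, rec_bad, "ch")
  ctr <- (seq_along(mask) - 0.5) * sp$hop
  inside <- ctr > 601 & ctr < 629
  expect_true(all(mask[inside]))
  expect_gt(mean(!mask[!inside]), 0.99)

  # brute-force oracle: recompute the outlier score of the total-power
  # feature directly (over interior bins) and compare the flags it
  # implies
  interior <- !sp$edge_bins
  v <- rowMeans(sp$power)
  z <- abs(v - median(v[interior])) / sd(v[interior])
  expect_true(all(mask[z > 4 & interior]))
})

test_that("a stationary record yields an empty mask", {
  fs <- 200
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(list(ch = 20 * sin(2 * pi * 9 * t)), fs)
  sp <- compute_spectrogram(rec, "ch")
  mask <- suppressWarnings(detect_noise_epochs(sp, rec, "ch"))
  expect_equal(sum(mask), 0L)
  # a statistically stationary (noise) record stays essentially clean
  set.seed(5)
  rec2 <- eeg_recording(list(ch = stats::rnorm(200 * 600)), 200)
  sp2 <- compute_spectrogram(rec2, "ch")
  mask2 <- suppressWarnings(detect_noise_epochs(sp2, rec2, "ch"))
  expect_lt(mean(mask2), 0.005)
})

test_that("mask fraction is invariant to overall gain", {
  rec <- pink_record(dur = 900)
  rec <- inject_artifacts(rec, data.frame(start_s = 400, duration_s = 30,
                                          gain = 20))
  rec2 <- rec
  rec2$samples$ch <- rec2$samples$ch * 7.3
  m1 <- detect_noise_epochs(compute_spectrogram(rec, "ch"), rec, "ch")
  m2 <- detect_noise_epochs(compute_spectrogram(rec2, "ch"), rec2, "ch")
  expect_equal(m1, m2)
})

test_that("constant signal warns and flags nothing", {
  rec <- eeg_recording(list(ch = rep(1, 200 * 600)), 200)
  sp <- compute_spectrogram(rec, "ch")
  w <- capture_warnings(mask <- detect_noise_epochs(sp, rec, "ch"))
  expect_match(w, "no meaningful spread", all = FALSE)
  expect_length(w, 2L)  # both features are flat on a constant signal
  expect_equal(sum(mask), 0L)
})

test_that("baselining zeroes per-frequency means over unmasked bins", {
  rec <- pink_record(dur = 600)
  sp <- compute_spectrogram(rec, "ch")
  mask <- seq_len(nrow(sp$power)) %in% 100:140
  b <- baseline_spectrogram(sp, mask)
  expect_true(b$baselined)
  cm <- colMeans(b$power[!mask, ])
  expect_lt(max(abs(cm)), 1e-9)
  # masked bins also have the baseline subtracted
  oracle <- sp$power - matrix(colMeans(sp$power[!mask, ]),
                              nrow(sp$power), ncol(sp$power),
                              byrow = TRUE)
  expect_equal(b$power, oracle, tolerance = 1e-12)
})

test_that("baselining a time-constant spectrogram yields zeros", {
  rec <- eeg_recording(list(ch = sin(2 * pi * 10 *
                                     seq(0, 600, by = 1 / 200))), 200)
  sp <- compute_spectrogram(rec, "ch")
  interior <- which(!sp$edge_bins)
  sp$power <- sp$power[interior, , drop = FALSE]  # keep steady state
  sp$edge_bins <- sp$edge_bins[interior]
  b <- baseline_spectrogram(sp)
  expect_lt(max(abs(colMeans(b$power))), 1e-9)
})

test_that("baselining twice or with a full mask is an error", {
  rec <- pink_record(dur = 600)
  sp <- compute_spectrogram(rec, "ch")
  b <- baseline_spectrogram(sp)
  expect_error(baseline_spectrogram(b), "already baselined")
  expect_error(baseline_spectrogram(sp, rep(TRUE, nrow(sp$power))),
               "all bins")
  expect_error(detect_noise_epochs(b), "non-baselined")
})

test_that("line-noise masking interpolates the 50-70 Hz rows only", {
  fs <- 250; dur <- 600
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  set.seed(2)
  x <- stats::rnorm(length(t)) + 5 * sin(2 * pi * 60 * t)
  sp <- compute_spectrogram(eeg_recording(list(ch = x), fs), "ch")
  masked <- mask_line_noise(sp, c(50, 70))
  inside <- sp$freqs > 50 & sp$freqs < 70
  below <- sp$freqs <= 50
  interior <- !sp$edge_bins
  # the 60 Hz ridge dominates the raw band but is gone after masking
  expect_gt(max(colMeans(sp$power[interior, inside])),
            max(colMeans(masked$power[interior, inside])) + 10)
  expect_equal(masked$power[, below], sp$power[, below])
  # grid without rows in the band -> identity
  bank <- design_wavelets(1, 40, 30)
  sp2 <- compute_spectrogram(eeg_recording(list(ch = x), fs), "ch", bank)
  m2 <- mask_line_noise(sp2, c(50, 70))
  expect_equal(m2$power, sp2$power)
})

test_that("the Wake feature ignores the line-noise band", {
  fs <- 250; dur <- 600
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  set.seed(7)
  base <- stats::rnorm(length(t))
  ridge <- 8 * sin(2 * pi * 60 * t)
  f1 <- band_features(baseline_spectrogram(
    compute_spectrogram(eeg_recording(list(ch = base), fs), "ch")))
  f2 <- band_features(baseline_spectrogram(
    compute_spectrogram(eeg_recording(list(ch = base + ridge), fs),
                        "ch")))
  # relative Wake feature unchanged by the ridge (baseline removes any
  # common offset; the 50-70 Hz rows are excluded from the average)
  expect_equal(f1$values[, "WAKE"], f2$values[, "WAKE"],
               tolerance = 0.05)
})
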