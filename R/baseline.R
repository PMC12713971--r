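#' Detect noise epochs from extreme RMS or total spectral power
#'
#' A 0.5-s bin is flagged as noise when the outlier score of either of
#' two features exceeds `z_thresh`: the windowed RMS of the raw signal
#' centred on the bin (in dB) or the bin's total spectrogram power (mean
#' dB across the frequency grid). The score is the deviation from the
#' night median in units of the feature's standard deviation. The median
#' centre is robust to artifact spans, while the SD scale is deliberately
#' *not* robust: it is inflated by the night's physiological stage
#' variation, so high-amplitude slow-wave sleep (routinely 4-6x the
#' night-median RMS) stays well inside the fence and only genuinely
#' extreme broadband excursions are flagged. Both features live on the
#' dB scale, so the flagged fraction does not depend on amplifier gain.
#'
#' @param spec A non-baselined `spectrogram`.
#' @param rec Optional `eeg_recording` supplying the raw signal for the
#'   RMS feature; if omitted only the spectral feature is used.
#' @param channel Channel to take RMS from (defaults to the first).
#' @param z_thresh Outlier score threshold; bins exceeding it on either
#'   feature are flagged.
#' @param rms_window Width in seconds of the RMS window.
#' @return Logical vector, one element per spectrogram time bin, with
#'   attribute `fraction` (flagged fraction). A constant feature (zero
#'   spread) contributes no flags and raises a warning.
#' @export
detect_noise_epochs <- function(spec, rec = NULL,
                                channel = if (!is.null(rec))
                                  rec$channel_labels[1] else NULL,
                                z_thresh = 4, rms_window = 2) {
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$baselined)
    stop("noise detection runs on the raw (non-baselined) spectrogram")
  n_bins <- nrow(spec$power)
  # the spectral feature skips edge bins (zero-padding transients there
  # are not artifacts); the raw-RMS feature still covers the whole record
  interior <- if (is.null(spec$edge_bins)) rep(TRUE, n_bins)
              else !spec$edge_bins
  feats <- list(total_db = rowMeans(spec$power))
  scope <- list(total_db = interior)
  if (!is.null(rec)) {
    x <- rec$samples[[channel]]
    if (is.null(x)) stop("unknown channel '", channel, "'")
    cs <- cumsum(c(0, x^2))
    half <- rms_window / 2
    ctr <- (seq_len(n_bins) - 0.5) * spec$hop
    i0 <- pmax(1L, as.integer(floor((ctr - half) * rec$fs)) + 1L)
    i1 <- pmin(length(x), as.integer(ceiling((ctr + half) * rec$fs)))
    rms <- sqrt((cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L))
    feats$rms_db <- 20 * log10(pmax(rms, 1e-12))
    scope$rms_db <- rep(TRUE, n_bins)
  }
  mask <- logical(n_bins)
  for (nm in names(feats)) {
    v <- feats[[nm]]
    in_scope <- scope[[nm]]
    s <- stats::sd(v[in_scope])
    # a night whose feature varies by < 0.5 dB is stationary for all
    # practical purposes: genuine artifacts are tens of dB excursions,
    # while sub-dB ripple (numerical floor noise, window roundoff) would
    # make z-scores explode over nothing
    if (s < 0.5) {
      warning("feature '", nm, "' has no meaningful spread ",
              "(stationary signal); no bins flagged from it")
      next
    }
    z <- abs(v - stats::median(v[in_scope])) / s
    mask <- mask | (in_scope & z > z_thresh)
  }
  attr(mask, "fraction") <- mean(mask)
  mask
}

#' Remove the whole-night baseline spectrum
#'
#' The baseline is the per-frequency mean dB over the entire night
#' excluding noise-masked bins. It is subtracted from every time bin
#' (masked bins included; they are excluded only from the average), so
#' the result is relative dB: 0 means "at this frequency, the night's
#' typical power".
#'
#' @param spec A non-baselined `spectrogram`.
#' @param mask Logical noise mask per time bin (e.g. from
#'   [detect_noise_epochs()]); `NULL` uses `spec$noise_mask` or no mask.
#' @return The baselined `spectrogram`, with `baseline` (the subtracted
#'   per-frequency vector) and `noise_mask` stored.
#' @export
baseline_spectrogram <- function(spec, mask = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$baselined) stop("spectrogram is already baselined")
  if (is.null(mask)) mask <- spec$noise_mask
  if (is.null(mask)) mask <- logical(nrow(spec$power))
  if (length(mask) != nrow(spec$power))
    stop("mask length does not match number of time bins")
  if (all(mask)) stop("all bins are noise-masked; no baseline available")
  base <- colMeans(spec$power[!mask, , drop = FALSE])
  spec$power <- sweep(spec$power, 2L, base)
  spec$baseline <- base
  spec$noise_mask <- mask
  spec$baselined <- TRUE
  spec
}

#' Mask line-noise frequencies for display
#'
#' Replaces spectrogram rows between `band[1]` and `band[2]` Hz (mains
#' interference and its spread) with a per-bin linear interpolation, in
#' log-frequency, between the nearest rows outside the band. Intended for
#' the display spectrogram only: scoring bands are computed from the
#' unmasked matrix, and the Wake band already skips these rows via its
#' exclusion list.
#'
#' @param spec A `spectrogram`.
#' @param band Length-2 numeric, Hz; rows strictly inside are replaced.
#' @return The spectrogram with interpolated rows and `line_mask_band`
#'   set. Identity when no grid frequency falls inside the band.
#' @export
mask_line_noise <- function(spec, band = c(50, 70)) {
  stopifnot(inherits(spec, "spectrogram"), length(band) == 2L)
  inside <- which(spec$freqs > band[1] & spec$freqs < band[2])
  if (length(inside)) {
    lo <- max(which(spec$freqs <= band[1]))
    hi <- min(which(spec$freqs >= band[2]))
    if (is.infinite(lo) || is.infinite(hi))
      stop("line band extends past the frequency grid")
    lf <- log10(spec$freqs)
    w <- (lf[inside] - lf[lo]) / (lf[hi] - lf[lo])
    spec$power[, inside] <-
      spec$power[, lo] %o% (1 - w) + spec$power[, hi] %o% w
  }
  spec$line_mask_band <- band
  spec
}
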