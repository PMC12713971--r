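#' Design a Morlet wavelet bank
#'
#' Frequencies are log-spaced on `[f_min, f_max]` and the number of cycles
#' per wavelet grows linearly in `log10(frequency)` from `c_min` at the
#' lowest frequency to `c_max` at the highest. The cycle gradient trades
#' temporal resolution at low frequencies (few cycles, short wavelets in
#' periods) against spectral resolution at high frequencies (many cycles),
#' which keeps slow-oscillation transients visible while separating the
#' spindle and beta bands.
#'
#' @param f_min,f_max Frequency range in Hz (0 < f_min < f_max).
#' @param n_freqs Number of grid frequencies (>= 2).
#' @param c_min,c_max Cycles at `f_min` and `f_max` (`c_min <= c_max`).
#' @return A `wavelet_bank`: list with `freqs` and `cycles`, both length
#'   `n_freqs`.
#' @examples
#' bank <- design_wavelets()
#' range(bank$cycles)  # 3 at 0.1 Hz, 30 at 100 Hz
#' @export
design_wavelets <- function(f_min = 0.1, f_max = 100, n_freqs = 100,
                            c_min = 3, c_max = 30) {
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 || f_min >= f_max)
    stop("need 0 < f_min < f_max")
  if (c_min > c_max) stop("c_min must not exceed c_max")
  if (n_freqs < 2) stop("n_freqs must be at least 2")
  lf <- seq(log10(f_min), log10(f_max), length.out = n_freqs)
  freqs <- 10^lf
  cycles <- c_min + (c_max - c_min) *
    (lf - lf[1]) / (lf[n_freqs] - lf[1])
  structure(list(freqs = freqs, cycles = cycles), class = "wavelet_bank")
}

# Gaussian time-domain std of a Morlet wavelet (s); its spectral std is
# f / cycles.
.sigma_t <- function(f, cycles) cycles / (2 * pi * f)

# smallest integer >= n whose prime factors are all in {2,3,5}; keeps the
# whole-night FFT length highly composite
.next_smooth <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Compute a whole-night Morlet wavelet spectrogram
#'
#' Decomposes one channel into time-frequency power on the bank's grid at
#' a fixed time step (`hop`, default 0.5 s). Each per-bin coefficient is a
#' complex Morlet amplitude; power is the coefficient multiplied by its
#' conjugate (squared magnitude), floored at `db_floor` and converted to
#' decibels as `10*log10(power)` (`mode = "amplitude"` instead logs the
#' magnitude, i.e. halves the dB scale).
#'
#' Implementation: one FFT of the zero-padded record, then per frequency
#' the spectrum is multiplied by the wavelet's Gaussian frequency response
#' (support `f +/- 4*f/cycles`) and inverted with a short FFT over just
#' that band, yielding the analytic band signal exactly at a reduced rate
#' aligned with the hop grid. Sampling the centre of each hop window gives
#' the per-bin coefficient. Zero padding means bins whose wavelet extends
#' past the record are computed against implicit zeros; those bins are
#' flagged in `edge_bins`.
#'
#' @param rec An `eeg_recording`.
#' @param channel Channel label to decompose.
#' @param bank A `wavelet_bank` from [design_wavelets()].
#' @param hop Time step in seconds; `2/hop` must be a whole number.
#' @param db_floor Power floor applied before the log so silence maps to a
#'   finite dB value.
#' @param mode `"power"` (default) or `"amplitude"` dB convention.
#' @return A `spectrogram`: `power` (time x frequency dB matrix), `freqs`,
#'   `hop`, `baselined` flag, `noise_mask` (filled in later), `edge_bins`,
#'   `line_mask_band`, `mode`.
#' @export
compute_spectrogram <- function(rec, channel = rec$channel_labels[1],
                                bank = design_wavelets(), hop = 0.5,
                                db_floor = 1e-12, mode = c("power",
                                                           "amplitude")) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(bank, "wavelet_bank"))
  mode <- match.arg(mode)
  if (!channel %in% rec$channel_labels)
    stop("unknown channel '", channel, "'; have: ",
         paste(rec$channel_labels, collapse = ", "))
  if (hop <= 0) stop("'hop' must be positive")
  m0 <- 2 / hop
  if (abs(m0 - round(m0)) > 1e-9)
    stop("2/hop must be a whole number (hop = 0.5, 0.25, 1, ... )")
  m0 <- as.integer(round(m0))
  fs <- rec$fs
  x <- rec$samples[[channel]]
  n <- length(x)
  dur <- n / fs
  t_half <- 4 * .sigma_t(bank$freqs[1], bank$cycles[1])
  if (dur < 2 * t_half)
    stop(sprintf(paste0("record (%.1f s) shorter than the longest wavelet",
                        " support (%.1f s)"), dur, 2 * t_half))
  n_bins <- floor(dur / hop)

  # pad past the longest wavelet so circular wrap cannot reach interior bins
  t_pad <- .next_smooth(ceiling(dur + 2 * t_half))
  N <- as.integer(round(t_pad * fs))
  X <- stats::fft(c(x, numeric(N - n)))
  half <- X[seq_len(N %/% 2 + 1L)]  # non-negative frequencies only

  nf <- length(bank$freqs)
  pow <- matrix(0, n_bins, nf)
  bins <- seq_len(n_bins) - 1L
  for (i in seq_len(nf)) {
    f <- bank$freqs[i]
    sig_f <- f / bank$cycles[i]
    # reduced rate: a multiple of 2/hop wide enough for a 14-sigma band;
    # at the window edge the Gaussian is ~2e-11, so the effective wavelet
    # carries no numerically relevant ringing beyond its Gaussian envelope
    fsd <- m0 * max(1L, as.integer(ceiling(14 * sig_f / m0)))
    Kp <- as.integer(round(t_pad * fsd))
    jc <- as.integer(round(f * t_pad))
    j0 <- max(0L, min(jc - Kp %/% 2L, N %/% 2L - Kp + 1L))
    jj <- j0 + seq_len(Kp) - 1L
    nu <- jj / t_pad
    H <- exp(-((nu - f)^2) / (2 * sig_f^2))
    H[nu <= 0 | nu > fs / 2] <- 0
    y <- stats::fft(half[jj + 1L] * H, inverse = TRUE) / N
    # centre of hop window t is (t + 0.5) * hop -> integer index at rate fsd
    idx <- bins * (hop * fsd) + fsd * hop / 2 + 1L
    yc <- y[as.integer(round(idx))]
    pow[, i] <- Re(yc * Conj(yc))
  }
  expo <- if (mode == "power") 10 else 5
  db <- expo * log10(pmax(pow, db_floor))

  centers <- (bins + 0.5) * hop
  edge <- centers < t_half | centers > dur - t_half
  structure(list(power = db, freqs = bank$freqs, hop = hop,
                 baselined = FALSE, noise_mask = NULL,
                 line_mask_band = NULL, edge_bins = edge,
                 db_floor = db_floor, mode = mode, fs = fs,
                 cycles = bank$cycles),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(paste0("<spectrogram> %d bins x %d freqs (%.2g-%.3g Hz),",
                     " hop %.2g s, %s%s\n"),
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              x$hop, if (x$baselined) "baselined" else "raw dB",
              if (!is.null(x$line_mask_band)) ", line-masked" else ""))
  invisible(x)
}
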