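#' Scoring band definitions
#'
#' The five spectral bands that summarise each epoch, named after the
#' stage each characterises: Wake 40-95 Hz (gamma), REM ~17-26 Hz (low
#' beta), Light ~11-15.5 Hz (sleep spindles), Hi Deep 1-3 Hz (delta) and
#' Lo Deep 0.1-1 Hz (slow oscillations). The Wake band carries the line
#' noise band as an exclusion so mains interference never contaminates
#' the gamma feature.
#'
#' @param wake,rem,light,hideep,lodeep Length-2 numeric `(lo, hi)` Hz.
#' @param line_band Sub-band excluded from the Wake average.
#' @return A named list of five `band_def` objects (fields `name`, `lo`,
#'   `hi`, `exclusions`), ordered as the stage vocabulary.
#' @export
band_definitions <- function(wake = c(40, 95), rem = c(17, 26),
                             light = c(11, 15.5), hideep = c(1, 3),
                             lodeep = c(0.1, 1), line_band = c(50, 70)) {
  mk <- function(name, range, exclusions = list()) {
    if (range[1] >= range[2])
      stop("band ", name, ": lo must be below hi")
    structure(list(name = name, lo = range[1], hi = range[2],
                   exclusions = exclusions), class = "band_def")
  }
  defs <- list(WAKE = mk("WAKE", wake, list(line_band)),
               REM = mk("REM", rem), LIGHT = mk("LIGHT", light),
               HIDEEP = mk("HIDEEP", hideep), LODEEP = mk("LODEEP", lodeep))
  defs[SPECTRAL_STAGES]
}

# frequency-grid selector for one band: inclusive range minus the open
# interior of each exclusion
.band_rows <- function(freqs, def) {
  sel <- freqs >= def$lo & freqs <= def$hi
  for (ex in def$exclusions) sel <- sel & !(freqs > ex[1] & freqs < ex[2])
  if (!any(sel))
    stop("band ", def$name, " [", def$lo, ", ", def$hi,
         "] contains no grid frequencies")
  which(sel)
}

#' Per-epoch five-band features
#'
#' Partitions the baselined spectrogram into fixed epochs (a trailing
#' partial epoch is dropped) and averages relative dB over each band's
#' grid rows and the epoch's time bins, yielding the epoch-by-5 feature
#' matrix the HMM stages on. Also records, per epoch, the mean total
#' power (all grid rows) used by the correction rules, and a noise flag
#' for epochs with at least half their bins noise-masked.
#'
#' @param spec A baselined `spectrogram`.
#' @param defs Band definitions from [band_definitions()].
#' @param epoch_len Epoch length in seconds (default 30; values down to
#'   ~10 s remain meaningful, below that the hypnogram becomes unstable).
#' @return A `band_series`: `values` (n_epochs x 5 matrix, columns in
#'   stage order), `epoch_len`, `band_defs`, `n_epochs`, `total_power`,
#'   `flagged`.
#' @export
band_features <- function(spec, defs = band_definitions(),
                          epoch_len = 30) {
  stopifnot(inherits(spec, "spectrogram"))
  if (!spec$baselined)
    stop("band features are defined on the baselined spectrogram")
  bpe <- epoch_len / spec$hop
  if (abs(bpe - round(bpe)) > 1e-9)
    stop("epoch_len must be a multiple of the spectrogram hop")
  bpe <- as.integer(round(bpe))
  n_epochs <- nrow(spec$power) %/% bpe
  if (n_epochs < 1L) stop("record shorter than one epoch")
  used <- seq_len(n_epochs * bpe)
  epoch_mean <- function(v)
    colMeans(matrix(v[used], nrow = bpe))
  vals <- vapply(defs, function(d) {
    epoch_mean(rowMeans(spec$power[, .band_rows(spec$freqs, d),
                                   drop = FALSE]))
  }, numeric(n_epochs))
  vals <- matrix(vals, nrow = n_epochs,
                 dimnames = list(NULL, names(defs)))
  total <- epoch_mean(rowMeans(spec$power))
  flagged <- if (!is.null(spec$noise_mask))
    epoch_mean(as.numeric(spec$noise_mask)) >= 0.5
  else rep(FALSE, n_epochs)
  structure(list(values = vals, epoch_len = epoch_len, band_defs = defs,
                 n_epochs = n_epochs, total_power = total,
                 flagged = flagged),
            class = "band_series")
}

#' @export
print.band_series <- function(x, ...) {
  cat(sprintf("<band_series> %d epochs x %d bands, epoch %g s (%d flagged)\n",
              x$n_epochs, ncol(x$values), x$epoch_len, sum(x$flagged)))
  invisible(x)
}

#' Refine the Light and REM bands around their observed peaks
#'
#' After a first scoring pass, the spindle and REM-beta peak frequencies
#' are located in the mean spectrum of the epochs scored Light and REM
#' respectively, and the bands re-centred: Light becomes
#' `[peak - 1, peak + 1.5]` Hz and REM `[peak - 2, peak + 2]` Hz. This
#' adapts the fixed default bands to each sleeper's individual spindle
#' and REM beta frequencies. A stage with no first-pass epochs leaves its
#' band unchanged.
#'
#' @param spec The baselined `spectrogram`.
#' @param first_pass A `hypnogram` from the first scoring pass.
#' @param defs Current band definitions.
#' @param spindle_search,rem_search `(lo, hi)` Hz windows searched for
#'   the respective peaks.
#' @return Updated band definitions.
#' @export
refine_band_peaks <- function(spec, first_pass, defs = band_definitions(),
                              spindle_search = c(9, 16),
                              rem_search = c(15, 30)) {
  stopifnot(inherits(spec, "spectrogram"), inherits(first_pass, "hypnogram"))
  if (!spec$baselined) stop("refinement needs the baselined spectrogram")
  bpe <- as.integer(round(first_pass$epoch_len / spec$hop))
  peak_for <- function(stage, search) {
    ep <- which(first_pass$stages == stage)
    if (!length(ep)) return(NULL)
    bins <- as.vector(outer(seq_len(bpe), (ep - 1L) * bpe, `+`))
    bins <- bins[bins <= nrow(spec$power)]
    rows <- which(spec$freqs >= search[1] & spec$freqs <= search[2])
    mean_spec <- colMeans(spec$power[bins, rows, drop = FALSE])
    spec$freqs[rows[which.max(mean_spec)]]
  }
  p_s <- peak_for("LIGHT", spindle_search)
  if (!is.null(p_s))
    defs$LIGHT <- structure(list(name = "LIGHT", lo = p_s - 1,
                                 hi = p_s + 1.5, exclusions = list()),
                            class = "band_def")
  p_r <- peak_for("REM", rem_search)
  if (!is.null(p_r))
    defs$REM <- structure(list(name = "REM", lo = p_r - 2, hi = p_r + 2,
                               exclusions = list()), class = "band_def")
  defs
}

#' Dominant frequency trace
#'
#' For each time bin, the grid frequency with maximal smoothed relative
#' power. Smoothing is a centred moving average over time (shrinking at
#' the record edges) applied before the argmax; ties resolve to the
#' lowest frequency. The trace highlights low-amplitude rhythms (e.g.
#' REM low beta) that the spectrogram colour scale can hide.
#'
#' @param spec A baselined (optionally line-masked) `spectrogram`.
#' @param smooth_window Moving-average width in seconds (default 40; one
#'   hop's width disables smoothing).
#' @return A `dominant_frequency_series`: `freq_at_max` (Hz per bin, a
#'   member of the grid) and `smoothing_window`.
#' @export
dominant_frequency <- function(spec, smooth_window = 40) {
  stopifnot(inherits(spec, "spectrogram"))
  w <- max(1L, as.integer(round(smooth_window / spec$hop)))
  m <- spec$power
  if (w > 1L) {
    half_lo <- (w - 1L) %/% 2L
    half_hi <- w %/% 2L
    n <- nrow(m)
    cs <- apply(m, 2L, function(v) cumsum(c(0, v)))
    i0 <- pmax(0L, seq_len(n) - 1L - half_lo)
    i1 <- pmin(n, seq_len(n) + half_hi)
    m <- (cs[i1 + 1L, , drop = FALSE] - cs[i0 + 1L, , drop = FALSE]) /
      (i1 - i0)
  }
  idx <- max.col(m, ties.method = "first")
  structure(list(freq_at_max = spec$freqs[idx],
                 smoothing_window = smooth_window),
            class = "dominant_frequency_series")
}
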