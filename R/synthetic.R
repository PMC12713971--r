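#' Define a stage script for the synthetic night generator
#'
#' A stage script lists the night as ordered `(stage, duration)` segments
#' plus the physical parameters of the simulation: sampling rate, a 1/f
#' (pink) background, and per-stage oscillation amplitudes. Durations
#' must be whole epochs and the night at least 10 epochs long.
#'
#' Default amplitudes (microvolts) are chosen so each stage's signature
#' band dominates its epochs while remaining in realistic proportion to
#' the 10 uV RMS pink background: Wake gamma 3, REM low beta 5, spindle
#' bursts 8, delta 40, slow oscillation 60.
#'
#' @param segments Data frame with columns `stage` (spectral vocabulary)
#'   and `duration_s`, or a list of `c(stage, duration)` pairs.
#' @param fs Sampling rate (Hz).
#' @param epoch_len Epoch length the durations must respect (s).
#' @param seed Integer seed; the same seed reproduces the night exactly.
#' @param amplitudes Named list of per-stage oscillation amplitudes (uV):
#'   `wake`, `rem`, `spindle`, `delta`, `slow_osc`, `lodeep_spindle`
#'   (the mild spindle content retained during Lo Deep).
#' @param background List with `exponent` (power ~ 1/f^exponent) and
#'   `rms` (uV).
#' @param spindle_hz Spindle carrier frequency (Hz).
#' @param rem_hz Centre of the REM low-beta rhythm (Hz).
#' @return A `stage_script`.
#' @export
stage_script <- function(segments, fs = 500, epoch_len = 30, seed = 1,
                         amplitudes = list(wake = 3, rem = 5, spindle = 8,
                                           delta = 40, slow_osc = 60,
                                           lodeep_spindle = 3),
                         background = list(exponent = 1, rms = 10),
                         spindle_hz = 13, rem_hz = 20) {
  segments <- as.data.frame(segments)
  if (!all(c("stage", "duration_s") %in% names(segments)))
    stop("'segments' needs columns stage, duration_s")
  bad <- setdiff(unique(segments$stage), SPECTRAL_STAGES)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  frac <- segments$duration_s / epoch_len
  if (any(abs(frac - round(frac)) > 1e-9))
    stop("segment durations must be whole epochs of ", epoch_len, " s")
  if (sum(segments$duration_s) < 10 * epoch_len)
    stop("script must cover at least 10 epochs")
  structure(list(segments = segments, fs = fs, epoch_len = epoch_len,
                 seed = as.integer(seed), amplitudes = amplitudes,
                 background = background, spindle_hz = spindle_hz,
                 rem_hz = rem_hz),
            class = "stage_script")
}

#' A realistic full-cycle stage script
#'
#' Eight-hour default: 10 min pre-sleep Wake, five 90-min cycles of
#' Light, Hi Deep, Lo Deep, Light, REM, then 20 min terminal Wake.
#' This is the canonical fixture for end-to-end recovery tests.
#'
#' @param n_cycles Number of sleep cycles.
#' @param seed Seed passed to [stage_script()].
#' @param ... Further arguments to [stage_script()].
#' @return A `stage_script` (8 h for the default 5 cycles).
#' @export
make_cycle_script <- function(n_cycles = 5, seed = 1, ...) {
  cycle <- data.frame(
    stage = c("LIGHT", "HIDEEP", "LODEEP", "LIGHT", "REM"),
    duration_s = c(25, 15, 20, 10, 20) * 60)
  segs <- rbind(data.frame(stage = "WAKE", duration_s = 600),
                do.call(rbind, replicate(n_cycles, cycle,
                                         simplify = FALSE)),
                data.frame(stage = "WAKE", duration_s = 1200))
  stage_script(segs, seed = seed, ...)
}

# band-limited Gaussian noise via FFT masking, scaled to target RMS
.bandpass_noise <- function(n, fs, lo, hi, rms) {
  if (n < 8L) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  X[!(f >= lo & f <= hi)] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * rms
}

# pink (1/f^expo power) background, zero-mean, scaled to target RMS
.pink_noise <- function(n, fs, expo, rms) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  f[1L] <- Inf                       # kill DC
  X <- X * f^(-expo / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

# 1-s Hann-windowed sinusoid bursts with centres every 4-6 s (jittered)
.spindle_train <- function(n, fs, f_hz, amp) {
  x <- numeric(n)
  len <- as.integer(fs)               # 1-s burst
  win <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
  tt <- seq_len(len) / fs
  pos <- 0
  while (TRUE) {
    pos <- pos + stats::runif(1, 4, 6)
    i0 <- as.integer(round(pos * fs))
    if (i0 + len > n) break
    x[i0 + seq_len(len)] <- x[i0 + seq_len(len)] +
      amp * win * sin(2 * pi * f_hz * tt + stats::runif(1, 0, 2 * pi))
  }
  x
}

#' Generate a synthetic night of sleep EEG with known stages
#'
#' Builds a single-channel recording as a pink-noise background plus
#' per-segment stage signatures on top: broadband gamma (40-95 Hz) for
#' Wake, a narrow low-beta rhythm (centre `rem_hz`) for REM, jittered
#' 1-s spindle bursts for Light, 1-3 Hz delta for Hi Deep and 0.4-0.9 Hz
#' slow oscillations (plus mild spindle content) for Lo Deep. The same
#' seed reproduces the night bit for bit, and the returned ground-truth
#' hypnogram matches the script exactly.
#'
#' @param script A `stage_script`.
#' @param channel Label given to the generated channel.
#' @return List with `recording` (an `eeg_recording`) and `hypnogram`
#'   (ground truth).
#' @export
generate_night <- function(script, channel = "FP1-AFz") {
  stopifnot(inherits(script, "stage_script"))
  set.seed(script$seed)
  fs <- script$fs
  segs <- script$segments
  total_s <- sum(segs$duration_s)
  n <- as.integer(round(total_s * fs))
  amp <- script$amplitudes
  x <- .pink_noise(n, fs, script$background$exponent,
                   script$background$rms)
  at <- 0L
  for (k in seq_len(nrow(segs))) {
    m <- as.integer(round(segs$duration_s[k] * fs))
    idx <- at + seq_len(m)
    sig <- switch(segs$stage[k],
      WAKE = .bandpass_noise(m, fs, 40, 95, amp$wake),
      REM = .bandpass_noise(m, fs, script$rem_hz - 1, script$rem_hz + 1,
                            amp$rem),
      LIGHT = .spindle_train(m, fs, script$spindle_hz, amp$spindle),
      HIDEEP = .bandpass_noise(m, fs, 1, 3, amp$delta),
      LODEEP = .bandpass_noise(m, fs, 0.4, 0.9, amp$slow_osc) +
        .spindle_train(m, fs, script$spindle_hz, amp$lodeep_spindle))
    x[idx] <- x[idx] + sig
    at <- at + m
  }
  rec <- eeg_recording(stats::setNames(list(x), channel), fs)
  truth <- hypnogram(rep(segs$stage, segs$duration_s / script$epoch_len),
                     epoch_len = script$epoch_len)
  list(recording = rec, hypnogram = truth)
}

#' Read a stage script from YAML
#'
#' The file holds `segments` (list of `stage`/`duration_s` entries) and
#' optionally any other [stage_script()] parameter.
#'
#' @param path YAML file path.
#' @param seed Overrides the file's seed when non-`NULL`.
#' @return A `stage_script`.
#' @export
read_stage_script <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$segments)) stop("script file lacks 'segments'")
  segs <- do.call(rbind, lapply(y$segments, function(s)
    data.frame(stage = s$stage, duration_s = s$duration_s)))
  args <- y[setdiff(names(y), "segments")]
  args$segments <- segs
  if (!is.null(seed)) args$seed <- seed
  do.call(stage_script, args)
}
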