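#' Score one EEG channel into a spectral hypnogram
#'
#' Runs the full pipeline on one channel: Morlet spectrogram (0.1-100
#' Hz, 0.5-s hop), noise-epoch detection, whole-night baseline removal,
#' five-band epoch features, HMM staging (argmax initialization, EM
#' refinement, maximal-posterior decoding), a second pass with the Light
#' and REM bands re-centred on the sleeper's own spindle and REM-beta
#' peaks, and finally the post-HMM correction rules.
#'
#' @param rec An `eeg_recording`.
#' @param channel Channel label to score (first channel by default).
#' @param config Configuration list, see [default_config()].
#' @return A `sleep_scoring` object: `hypnogram` (final), `first_pass`
#'   (pre-refinement, pre-correction hypnogram), `bands` (second-pass
#'   `band_series`), `band_defs` (refined), `spectrogram` (baselined),
#'   `display` (baselined + line-masked), `dominant`
#'   (`dominant_frequency_series`), `model` (fitted `hmm_model`),
#'   `posterior`, `noise_mask`, `channel`, `config`.
#' @export
score_recording <- function(rec, channel = rec$channel_labels[1],
                            config = default_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  cfg <- config
  bank <- design_wavelets(cfg$f_min, cfg$f_max, cfg$n_freqs,
                          cfg$c_min, cfg$c_max)
  raw <- compute_spectrogram(rec, channel, bank, hop = cfg$hop_s,
                             db_floor = cfg$db_floor, mode = cfg$db_mode)
  mask <- detect_noise_epochs(raw, rec, channel,
                              z_thresh = cfg$z_thresh,
                              rms_window = cfg$rms_window_s)
  spec <- baseline_spectrogram(raw, mask)
  defs <- do.call(band_definitions,
                  c(cfg$bands, list(line_band = cfg$line_band)))

  run_pass <- function(defs) {
    bands <- band_features(spec, defs, epoch_len = cfg$epoch_len_s)
    model <- init_hmm(bands, sticky = cfg$hmm$sticky,
                      var_floor = cfg$hmm$var_floor,
                      pi_wake = cfg$hmm$pi_wake)
    model <- em_fit(model, bands, max_iter = cfg$hmm$max_iter,
                    tol = cfg$hmm$tol)
    dec <- posterior_decode(model, bands)
    list(bands = bands, model = model, hyp = dec$hypnogram,
         posterior = dec$posterior)
  }

  pass1 <- run_pass(defs)
  final <- pass1
  if (isTRUE(cfg$refine)) {
    defs <- refine_band_peaks(spec, pass1$hyp, defs,
                              spindle_search = cfg$spindle_search,
                              rem_search = cfg$rem_search)
    final <- run_pass(defs)
  }
  hyp <- final$hyp
  if (isTRUE(cfg$correct))
    hyp <- apply_corrections(hyp, final$bands, cfg$thresholds)

  display <- mask_line_noise(spec, cfg$line_band)
  dom <- dominant_frequency(display, smooth_window = cfg$smooth_window_s)
  structure(list(hypnogram = hyp, first_pass = pass1$hyp,
                 bands = final$bands, band_defs = defs,
                 spectrogram = spec, display = display, dominant = dom,
                 model = final$model, posterior = final$posterior,
                 noise_mask = mask, channel = channel, config = cfg),
            class = "sleep_scoring")
}

#' @export
print.sleep_scoring <- function(x, ...) {
  cat(sprintf("<sleep_scoring> channel %s\n", x$channel))
  print(x$hypnogram)
  d <- stage_durations(x$hypnogram)
  cat("hours:", paste(sprintf("%s %.2f", names(d), d), collapse = ", "),
      "\n")
  invisible(x)
}
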