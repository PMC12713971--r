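# stage -> vertical position for hypnogram panels (deep sleep lowest)
.stage_y <- function(stages, labels) {
  y <- stats::setNames(rev(seq_along(labels)), labels)
  unname(y[stages])
}

# change-marker colours: the dot colour encodes the stage the epoch was
# changed FROM (green = Wake, red = REM, cyan = Light, blue = Hi/Lo Deep)
.changed_col <- c(WAKE = "green3", REM = "red", LIGHT = "cyan3",
                  HIDEEP = "blue", LODEEP = "blue")

.plot_hypnogram_panel <- function(hyp, hours, title, dots = FALSE) {
  labels <- hyp$labels
  y <- .stage_y(hyp$stages, labels)
  t <- (seq_along(y) - 0.5) * hyp$epoch_len / 3600
  plot(NA, xlim = c(0, hours), ylim = c(0.2, length(labels) + 0.3),
       xlab = "", ylab = "", axes = FALSE, main = title)
  graphics::axis(2, at = rev(seq_along(labels)), labels = labels,
                 las = 1, cex.axis = 0.8)
  graphics::box()
  graphics::lines(t, y, type = "s", lwd = 1.2, col = "grey20")
  if (dots) {
    ch <- which(!is.na(hyp$changed_from))
    if (length(ch))
      graphics::points(t[ch], rep(0.45, length(ch)), pch = 16,
                       cex = 0.6,
                       col = .changed_col[hyp$changed_from[ch]])
  }
}

#' Render a whole-night sleep report
#'
#' Stacked panels on a shared time axis: an optional reference (visual)
#' hypnogram, the spectral hypnogram with change-marker dots colour-coded
#' by the pre-correction stage, the whole-night relative-dB spectrogram
#' on a log-frequency axis, and the dominant-frequency trace.
#'
#' @param scoring A `sleep_scoring` from [score_recording()].
#' @param path Output PNG path.
#' @param ref_hyp Optional reference `hypnogram` (e.g. visual scoring).
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_report <- function(scoring, path, ref_hyp = NULL, width = 1600,
                          height = 1000) {
  stopifnot(inherits(scoring, "sleep_scoring"))
  spec <- scoring$display
  hyp <- scoring$hypnogram
  hours <- nrow(spec$power) * spec$hop / 3600
  n_panel <- 3L + !is.null(ref_hyp)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n_panel, 1),
                mar = c(2.2, 5, 2, 1), oma = c(2, 0, 0, 0))
  if (!is.null(ref_hyp))
    .plot_hypnogram_panel(ref_hyp, hours, "Reference (visual) scoring")
  .plot_hypnogram_panel(hyp, hours, sprintf("Spectral scoring (%s)",
                                            scoring$channel),
                        dots = TRUE)
  # spectrogram: decimate time bins for plotting
  m <- spec$power
  step <- max(1L, nrow(m) %/% 2000L)
  keep <- seq(1L, nrow(m), by = step)
  zlim <- stats::quantile(m, c(0.02, 0.999))
  z <- pmin(pmax(m[keep, , drop = FALSE], zlim[1]), zlim[2])
  graphics::image(x = keep * spec$hop / 3600, y = log10(spec$freqs),
                  z = z, col = grDevices::hcl.colors(64, "Spectral",
                                                     rev = TRUE),
                  xlab = "", ylab = "frequency (Hz)", axes = FALSE,
                  main = "Spectrogram (relative dB)")
  at <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  graphics::axis(2, at = log10(at), labels = at, las = 1,
                 cex.axis = 0.8)
  graphics::axis(1); graphics::box()
  dom <- scoring$dominant
  tt <- (seq_along(dom$freq_at_max) - 0.5) * spec$hop / 3600
  plot(tt, log10(dom$freq_at_max), pch = ".", col = "blue4",
       xlim = c(0, hours), xlab = "", ylab = "frequency (Hz)",
       axes = FALSE, main = "Dominant frequency")
  graphics::axis(2, at = log10(at), labels = at, las = 1,
                 cex.axis = 0.8)
  graphics::axis(1); graphics::box()
  graphics::mtext("time (h)", side = 1, outer = TRUE, line = 0.5)
  invisible(path)
}
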