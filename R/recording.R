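#' Construct an EEG recording
#'
#' Container for raw EEG: one numeric vector of samples (microvolts) per
#' channel, a common sampling rate and a start time. All channels must be
#' the same length and contain no missing values; forehead patch devices
#' write continuous records, so a NaN run indicates a corrupt ingest and is
#' rejected rather than repaired.
#'
#' @param samples Named list of numeric vectors (one per channel), or a
#'   single numeric vector together with `channel_labels`.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Channel names; defaults to `names(samples)`.
#' @param start_time `POSIXct` start of the recording.
#' @return An object of class `eeg_recording` with fields `samples`
#'   (named list), `fs`, `channel_labels` and `start_time`.
#' @export
eeg_recording <- function(samples, fs, channel_labels = NULL,
                          start_time = as.POSIXct("2024-01-01 22:00:00",
                                                  tz = "UTC")) {
  if (is.numeric(samples)) samples <- list(samples)
  if (!is.list(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty list of numeric vectors")
  if (is.null(channel_labels)) channel_labels <- names(samples)
  if (is.null(channel_labels) || any(!nzchar(channel_labels)))
    stop("every channel needs a label")
  if (length(channel_labels) != length(samples))
    stop("length of 'channel_labels' must match number of channels")
  names(samples) <- channel_labels
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  n <- vapply(samples, length, integer(1))
  if (length(unique(n)) != 1L)
    stop("all channels must have equal length; got ",
         paste(n, collapse = ", "))
  bad <- vapply(samples, function(x) anyNA(x) || any(!is.finite(x)),
                logical(1))
  if (any(bad))
    stop("non-finite samples in channel(s): ",
         paste(channel_labels[bad], collapse = ", "))
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.1f s at %g Hz\n",
              length(x$samples),
              paste(x$channel_labels, collapse = ", "),
              n / x$fs, x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples[[1]]) / rec$fs

#' Derive the FP2-AFz channel from the two FP1-referenced channels
#'
#' Forehead patch devices record FP1-AFz and FP1-FP2 against the FP1
#' reference; the third bipolar derivation follows by channel algebra:
#' FP2-AFz = (FP1-AFz) - (FP1-FP2), sample-wise.
#'
#' @param rec An `eeg_recording` containing channels named by `minuend`
#'   and `subtrahend`.
#' @param minuend,subtrahend,derived Channel labels involved in the
#'   subtraction; defaults follow the patch montage.
#' @return The recording with the derived channel appended.
#' @export
derive_third_channel <- function(rec, minuend = "FP1-AFz",
                                 subtrahend = "FP1-FP2",
                                 derived = "FP2-AFz") {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(c(minuend, subtrahend), rec$channel_labels)
  if (length(missing))
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  if (derived %in% rec$channel_labels)
    stop("channel '", derived, "' already present")
  rec$samples[[derived]] <- rec$samples[[minuend]] - rec$samples[[subtrahend]]
  rec$channel_labels <- c(rec$channel_labels, derived)
  rec
}

#' Scale time spans of a recording to emulate movement or contact artifacts
#'
#' Each span `(start_s, duration_s, gain)` multiplies the raw samples of
#' every channel within `[start_s, start_s + duration_s)` by `gain`;
#' samples outside all spans are untouched. Used to exercise noise-epoch
#' detection and baseline exclusion on synthetic nights.
#'
#' @param rec An `eeg_recording`.
#' @param spans Data frame with columns `start_s`, `duration_s`, `gain`.
#' @return The modified recording.
#' @export
inject_artifacts <- function(rec, spans) {
  stopifnot(inherits(rec, "eeg_recording"))
  spans <- as.data.frame(spans)
  need <- c("start_s", "duration_s", "gain")
  if (!all(need %in% names(spans)))
    stop("'spans' needs columns ", paste(need, collapse = ", "))
  n <- length(rec$samples[[1]])
  for (k in seq_len(nrow(spans))) {
    i0 <- floor(spans$start_s[k] * rec$fs) + 1L
    i1 <- min(n, floor((spans$start_s[k] + spans$duration_s[k]) * rec$fs))
    if (i0 > n || i1 < i0) next
    for (ch in rec$channel_labels)
      rec$samples[[ch]][i0:i1] <- rec$samples[[ch]][i0:i1] * spans$gain[k]
  }
  rec
}
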