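# European Data Format (EDF) input/output.
#
# EDF stores a fixed-width ASCII header (256 bytes plus 256 per signal)
# followed by data records of 16-bit little-endian integers; physical
# values are recovered by the per-signal linear digital->physical map.
# Implemented here directly against the format definition since the
# surrounding toolchain has no EDF support; only continuous,
# equal-sampling-rate EEG records are in scope (EDF+ annotations and
# discontinuous records are not).

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Uses 1-s data records (so `fs` must be a whole number of samples per
#' second) and per-channel physical ranges taken from the data; with the
#' 16-bit digital range this quantizes samples to
#' `(max - min) / 65535` of each channel's span. A trailing partial
#' second is zero-padded to complete the last record.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writing requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(rec$samples)
  n <- length(rec$samples[[1]])
  n_rec <- as.integer(ceiling(n / fs))
  st <- as.POSIXlt(rec$start_time)
  pmin_ <- vapply(rec$samples, min, numeric(1))
  pmax_ <- vapply(rec$samples, max, numeric(1))
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad(paste("Startdate", format(st, "%d-%b-%Y"), "X X X"), 80),
    format(st, "%d.%m.%y"),
    format(st, "%H.%M.%S"),
    .edf_pad(256 * (ns + 1L), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  fld <- function(vals, width)
    paste(vapply(vals, .edf_pad, character(1), width = width),
          collapse = "")
  hdr <- paste0(hdr,
    fld(rec$channel_labels, 16),
    fld(rep("", ns), 80),
    fld(rep("uV", ns), 8),
    paste(vapply(pmin_, .edf_num, character(1), width = 8), collapse = ""),
    paste(vapply(pmax_, .edf_num, character(1), width = 8), collapse = ""),
    fld(rep(-32768L, ns), 8),
    fld(rep(32767L, ns), 8),
    fld(rep("", ns), 80),
    fld(rep(fs, ns), 8),
    fld(rep("", ns), 32))
  writeBin(charToRaw(hdr), con)
  # re-read the header's physical limits so the scaling we apply is
  # exactly what a reader will recover from the truncated ASCII fields
  pmin_h <- as.numeric(vapply(pmin_, .edf_num, character(1), width = 8))
  pmax_h <- as.numeric(vapply(pmax_, .edf_num, character(1), width = 8))
  dig <- vector("list", ns)
  for (k in seq_len(ns)) {
    x <- rec$samples[[k]]
    if (length(x) < n_rec * fs) x <- c(x, numeric(n_rec * fs - length(x)))
    g <- (pmax_h[k] - pmin_h[k]) / 65535
    d <- as.integer(round((x - pmin_h[k]) / g) - 32768L)
    dig[[k]] <- pmin(32767L, pmax(-32768L, d))
  }
  blk <- matrix(0L, fs * ns, n_rec)
  for (k in seq_len(ns))
    blk[(k - 1L) * fs + seq_len(fs), ] <- matrix(dig[[k]], fs, n_rec)
  writeBin(as.integer(blk), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into an `eeg_recording`
#'
#' Requires every signal to share one sampling rate (true of forehead
#' patch records); mismatched rates raise an error naming the channels.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  main <- readBin(con, "raw", 256)
  if (length(main) < 256) stop("malformed EDF header (file too short)")
  fld <- function(raw, at, w) trimws(rawToChar(raw[at:(at + w - 1L)]))
  startdate <- fld(main, 169, 8)
  starttime <- fld(main, 177, 8)
  n_rec <- suppressWarnings(as.integer(fld(main, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(main, 245, 8)))
  ns <- suppressWarnings(as.integer(fld(main, 253, 4)))
  if (is.na(ns) || is.na(n_rec) || is.na(rec_dur))
    stop("malformed EDF header (non-numeric record fields)")
  if (ns < 1L) stop("EDF file has no signals")
  sig <- readBin(con, "raw", 256 * ns)
  if (length(sig) < 256 * ns)
    stop("malformed EDF header (truncated signal headers)")
  grab <- function(offset, w)
    vapply(seq_len(ns), function(k)
      fld(sig, offset * ns + (k - 1L) * w + 1L, w), character(1))
  labels <- grab(0, 16)
  pmin_ <- as.numeric(grab(104, 8))
  pmax_ <- as.numeric(grab(112, 8))
  dmin <- as.numeric(grab(120, 8))
  dmax <- as.numeric(grab(128, 8))
  spr <- suppressWarnings(as.integer(grab(216, 8)))
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)))
    stop("malformed EDF signal headers")
  fs_ch <- spr / rec_dur
  if (length(unique(fs_ch)) != 1L)
    stop("channels have different sampling rates: ",
         paste(sprintf("%s=%g Hz", labels, fs_ch), collapse = ", "))
  dat <- readBin(con, "integer", n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dat) < n_rec * sum(spr))
    stop("EDF data section shorter than the header promises")
  arr <- array(dat, dim = c(spr[1], ns, n_rec))
  samples <- vector("list", ns)
  for (k in seq_len(ns)) {
    g <- (pmax_[k] - pmin_[k]) / (dmax[k] - dmin[k])
    samples[[k]] <- as.vector(arr[, k, ]) * g + (pmin_[k] - dmin[k] * g)
  }
  start <- tryCatch(
    as.POSIXct(paste(startdate, starttime), tz = "UTC",
               format = "%d.%m.%y %H.%M.%S"),
    error = function(e) NA)
  if (is.na(start)) start <- as.POSIXct("2024-01-01 22:00:00", tz = "UTC")
  eeg_recording(samples, fs = fs_ch[1], channel_labels = labels,
                start_time = start)
}
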