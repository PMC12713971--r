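#' Construct a hypnogram
#'
#' Per-epoch stage labels, with optional change markers recording the
#' pre-correction stage of epochs altered by [apply_corrections()].
#' Epochs are 0-based and cover half-open intervals
#' `[i * epoch_len, (i+1) * epoch_len)` from the recording start.
#'
#' @param stages Character vector of per-epoch labels.
#' @param epoch_len Epoch length in seconds.
#' @param labels Allowed stage vocabulary; defaults to the spectral
#'   stages, use [VISUAL_STAGES] for AASM reference hypnograms.
#' @param changed_from Optional character vector (NA where unchanged)
#'   of pre-correction stages.
#' @param sleep_onset_epoch Optional 0-based index of sleep onset.
#' @return A `hypnogram` object.
#' @export
hypnogram <- function(stages, epoch_len = 30, labels = SPECTRAL_STAGES,
                      changed_from = NULL, sleep_onset_epoch = NULL) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), labels)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (is.null(changed_from)) changed_from <- rep(NA_character_,
                                                 length(stages))
  if (length(changed_from) != length(stages))
    stop("changed_from must match the number of epochs")
  same <- !is.na(changed_from) & changed_from == stages
  if (any(same))
    stop("changed_from must differ from the final stage where present")
  structure(list(stages = stages, epoch_len = epoch_len, labels = labels,
                 changed_from = changed_from,
                 sleep_onset_epoch = sleep_onset_epoch),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = x$labels))
  cat(sprintf("<hypnogram> %d epochs x %g s (%s)%s\n", length(x$stages),
              x$epoch_len,
              paste(names(tab), tab, sep = ":", collapse = " "),
              if (any(!is.na(x$changed_from)))
                sprintf(", %d corrected", sum(!is.na(x$changed_from)))
              else ""))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Write or read a hypnogram CSV
#'
#' Columns `epoch_index` (0-based), `start_sec`, `stage`, `changed_from`
#' (empty where the epoch was not corrected). Reading an empty file or a
#' file with unknown stage tokens is an error.
#'
#' @param hyp A `hypnogram`.
#' @param path File path.
#' @param labels Stage vocabulary accepted on read.
#' @param epoch_len Epoch length override on read; default infers it
#'   from the `start_sec` column (30 s for a single-epoch file).
#' @return `write_hypnogram` returns `path` invisibly; `read_hypnogram`
#'   returns a `hypnogram`.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$stages)
  df <- data.frame(epoch_index = seq_len(n) - 1L,
                   start_sec = (seq_len(n) - 1L) * hyp$epoch_len,
                   stage = hyp$stages,
                   changed_from = ifelse(is.na(hyp$changed_from), "",
                                         hyp$changed_from))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, labels = SPECTRAL_STAGES,
                           epoch_len = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse hypnogram file ",
                                          path, ": ", conditionMessage(e)))
  need <- c("epoch_index", "start_sec", "stage")
  if (nrow(df) == 0L || !all(need %in% names(df)))
    stop("hypnogram file ", path, " is empty or lacks columns ",
         paste(need, collapse = ", "))
  if (is.null(epoch_len))
    epoch_len <- if (nrow(df) > 1L) diff(df$start_sec[1:2]) else 30
  cf <- if ("changed_from" %in% names(df)) {
    v <- as.character(df$changed_from)
    v[!nzchar(v) | is.na(v)] <- NA_character_
    v
  } else NULL
  hypnogram(df$stage, epoch_len = epoch_len, labels = labels,
            changed_from = cf)
}
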