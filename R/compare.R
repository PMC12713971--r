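#' Confusion matrix between two hypnograms
#'
#' Tallies aligned epoch pairs: rows are the reference stages (e.g. the
#' visual AASM vocabulary, or ground truth), columns the test (spectral)
#' stages. Epochs are paired by index from a common start; when one
#' record is shorter, the overlap is used. There need be no "true"
#' labelling here - the matrix is simply a concise view of how the two
#' scorings relate, including reference stages (like N1) that have no
#' spectral equivalent.
#'
#' @param ref,test `hypnogram` objects with equal epoch length.
#' @return A `confusion_matrix`: integer `counts` with `row_labels` and
#'   `col_labels` taken from each hypnogram's vocabulary.
#' @export
confusion <- function(ref, test) {
  stopifnot(inherits(ref, "hypnogram"), inherits(test, "hypnogram"))
  if (ref$epoch_len != test$epoch_len)
    stop("epoch lengths differ (", ref$epoch_len, " vs ",
         test$epoch_len, " s)")
  n <- min(length(ref$stages), length(test$stages))
  counts <- table(factor(ref$stages[seq_len(n)], levels = ref$labels),
                  factor(test$stages[seq_len(n)], levels = test$labels))
  counts <- matrix(as.integer(counts), nrow = length(ref$labels),
                   dimnames = list(ref = ref$labels, test = test$labels))
  structure(list(counts = counts, row_labels = ref$labels,
                 col_labels = test$labels, n_epochs = n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d aligned epochs\n", x$n_epochs))
  print(x$counts)
  invisible(x)
}

#' Convert confusion counts to percentages along rows or columns
#'
#' Row direction: each row sums to 100, i.e. "of the epochs the
#' reference called stage r, what share did the test scoring give each
#' stage". Column direction is the converse. A stage with no epochs
#' (zero row/column total) has no defined percentage and is reported as
#' `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @param direction `"rows"` or `"columns"`.
#' @return Numeric matrix of percentages with the same dimnames.
#' @export
percentize <- function(cm, direction = c("rows", "columns")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  direction <- match.arg(direction)
  m <- cm$counts
  if (direction == "rows") {
    tot <- rowSums(m)
    out <- sweep(m, 1L, tot, "/") * 100
    out[tot == 0, ] <- NA_real_
  } else {
    tot <- colSums(m)
    out <- sweep(m, 2L, tot, "/") * 100
    out[, tot == 0] <- NA_real_
  }
  out
}

#' Pool percentage matrices across subjects by cell-wise medians
#'
#' Subjects contribute one percentage matrix each; the pooled summary is
#' the cell-wise median, with cell-wise quartiles for box-style range
#' displays. Cells undefined for a subject (empty stage) are ignored.
#'
#' @param per_subject List of equally-shaped percentage matrices.
#' @return List with `median`, `q25`, `q75` matrices.
#' @export
pool_medians <- function(per_subject) {
  stopifnot(is.list(per_subject), length(per_subject) >= 1L)
  d <- dim(per_subject[[1]])
  ok <- vapply(per_subject, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all matrices must have the same shape")
  arr <- array(unlist(per_subject), dim = c(d, length(per_subject)))
  q <- function(p) {
    out <- apply(arr, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else
        stats::quantile(v, p, na.rm = TRUE, names = FALSE))
    dimnames(out) <- dimnames(per_subject[[1]])
    out
  }
  list(median = q(0.5), q25 = q(0.25), q75 = q(0.75))
}

#' Average confusion counts cell-wise
#'
#' Used to combine per-channel matrices (e.g. the two forehead
#' derivations) into a single table without favouring either channel.
#'
#' @param cms List of `confusion_matrix` objects with identical labels.
#' @return Numeric matrix of mean counts.
#' @export
average_counts <- function(cms) {
  stopifnot(is.list(cms), length(cms) >= 1L)
  base <- cms[[1]]
  for (cm in cms[-1]) {
    stopifnot(inherits(cm, "confusion_matrix"))
    if (!identical(cm$row_labels, base$row_labels) ||
        !identical(cm$col_labels, base$col_labels))
      stop("confusion matrices have different labels")
  }
  Reduce(`+`, lapply(cms, `[[`, "counts")) / length(cms)
}

#' Time spent in each stage
#'
#' @param hyp A `hypnogram`.
#' @return Named numeric vector of hours per stage (all vocabulary
#'   stages, zero where unvisited); sums to the record length.
#' @export
stage_durations <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  tab <- table(factor(hyp$stages, levels = hyp$labels))
  stats::setNames(as.numeric(tab) * hyp$epoch_len / 3600, hyp$labels)
}

#' Write a confusion matrix (and its percentages) to CSV
#'
#' Writes `<prefix>.csv` with the raw counts and, when `percent = TRUE`,
#' `<prefix>.rowpct.csv` / `<prefix>.colpct.csv` with the row- and
#' column-percentage matrices.
#'
#' @param cm A `confusion_matrix`.
#' @param prefix Output path prefix.
#' @param percent Also write the percentage matrices.
#' @return The paths written, invisibly.
#' @export
write_confusion <- function(cm, prefix, percent = TRUE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  paths <- paste0(prefix, ".csv")
  utils::write.csv(cm$counts, paths[1])
  if (percent) {
    p <- paste0(prefix, c(".rowpct.csv", ".colpct.csv"))
    utils::write.csv(percentize(cm, "rows"), p[1])
    utils::write.csv(percentize(cm, "columns"), p[2])
    paths <- c(paths, p)
  }
  invisible(paths)
}
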