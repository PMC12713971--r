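#' Locate initial sleep onset
#'
#' Sleep onset is the first epoch of the first run of at least `run_len`
#' consecutive non-Wake epochs (default 10 epochs = 5 min of continuous
#' sleep). Used to gate the Wake-to-NREM correction rule, which must not
#' fire on genuine pre-sleep wakefulness.
#'
#' @param hyp A `hypnogram`.
#' @param run_len Minimum run length in epochs.
#' @return 0-based epoch index, or `NA_integer_` when no such run exists.
#' @export
find_sleep_onset <- function(hyp, run_len = 10) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(hyp$stages != "WAKE")
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_len)
  if (!length(hit)) return(NA_integer_)
  as.integer(ends[hit[1]] - r$lengths[hit[1]])
}

#' Default thresholds for the post-HMM correction rules
#'
#' All thresholds are on the baselined (relative dB) scale, so the same
#' defaults transfer across recordings and amplifier gains.
#' `ratio_db`: minimum beta-minus-spindle difference for rule 1;
#' `spindle_db`: spindle power below this counts as "relatively low"
#' (0 = at the night's baseline); `total_db`: elevation of an epoch's
#' whole-spectrum mean above the night median that counts as "total
#' power is high" for rule 2 (set well above what genuine slow-wave
#' sleep produces, since high-amplitude delta alone raises the
#' whole-spectrum mean by several dB, while broadband artifacts exceed
#' this easily); `delta_db`/`spindle_high_db`: elevations that count as
#' "sufficiently high" delta or spindle power for rule 4; `onset_run`:
#' run length defining sleep onset.
#'
#' @return Named list of thresholds.
#' @export
correction_thresholds <- function() {
  list(ratio_db = 2, spindle_db = 0, total_db = 15,
       delta_db = 2, spindle_high_db = 2, onset_run = 10)
}

#' Apply post-HMM correction rules for irregular sleep expressions
#'
#' Four rules re-examine each decoded epoch against its band features,
#' in order; the first rule that triggers changes the epoch, a single
#' time (no cascading re-evaluation), and the pre-correction stage is
#' recorded in `changed_from`:
#'
#' 1. Lo/Hi Deep becomes REM (or Wake, when the gamma band exceeds the
#'    beta band) when the beta-to-spindle ratio is high and total spindle
#'    power is relatively low - deep staging driven by low frequencies
#'    while the upper spectrum says otherwise.
#' 2. Lo/Hi Deep becomes Wake when total power is high and spindles are
#'    relatively low - broadband noise, not sleep.
#' 3. Lo/Hi Deep becomes Light when spindle power exceeds the low
#'    frequency power.
#' 4. Wake becomes Hi Deep or Light (whichever band is stronger) when
#'    delta or spindle power is sufficiently high - but only after
#'    initial sleep onset, so pre-sleep wake is never converted. This
#'    also covers restoring to NREM those epochs whose gamma band pulled
#'    them to Wake despite clear low-frequency sleep rhythms.
#'
#' Epochs that already carry a `changed_from` marker are left alone, and
#' the sleep-onset index is computed once (or reused when the input
#' already stores one), so re-applying the corrections is a no-op.
#'
#' @param hyp The decoded `hypnogram`.
#' @param bands The `band_series` the HMM was run on (same epochs).
#' @param thresholds Named list as [correction_thresholds()]; all keys
#'   are required.
#' @return The corrected `hypnogram` with `changed_from` markers and
#'   `sleep_onset_epoch` set.
#' @export
apply_corrections <- function(hyp, bands,
                              thresholds = correction_thresholds()) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(bands, "band_series"))
  if (length(hyp$stages) != bands$n_epochs)
    stop("hypnogram (", length(hyp$stages), ") and band series (",
         bands$n_epochs, ") have different epoch counts")
  missing <- setdiff(names(correction_thresholds()), names(thresholds))
  if (length(missing))
    stop("missing correction threshold(s): ",
         paste(missing, collapse = ", "))
  th <- thresholds
  onset <- hyp$sleep_onset_epoch
  if (is.null(onset)) onset <- find_sleep_onset(hyp, th$onset_run)
  X <- bands$values
  tot_med <- stats::median(bands$total_power)
  stages <- hyp$stages
  changed <- hyp$changed_from
  for (e in seq_along(stages)) {
    if (!is.na(changed[e])) next
    s <- stages[e]
    b <- X[e, ]
    new <- NA_character_
    if (s %in% .DEEP_STAGES) {
      if (b["REM"] - b["LIGHT"] >= th$ratio_db &&
          b["LIGHT"] < th$spindle_db) {                       # rule 1
        new <- if (b["WAKE"] > b["REM"]) "WAKE" else "REM"
      } else if (bands$total_power[e] >= tot_med + th$total_db &&
                 b["LIGHT"] < th$spindle_db) {                # rule 2
        new <- "WAKE"
      } else if (b["LIGHT"] > max(b["HIDEEP"], b["LODEEP"])) { # rule 3
        new <- "LIGHT"
      }
    } else if (s == "WAKE" && !is.na(onset) && e - 1L >= onset &&
               (b["HIDEEP"] >= th$delta_db ||
                b["LIGHT"] >= th$spindle_high_db)) {           # rule 4
      new <- if (b["HIDEEP"] >= b["LIGHT"]) "HIDEEP" else "LIGHT"
    }
    if (!is.na(new) && new != s) {
      changed[e] <- s
      stages[e] <- new
    }
  }
  # onset is stored even when absent (NA) so that re-application reuses
  # this pass's gate instead of recomputing it from corrected stages
  hypnogram(stages, epoch_len = hyp$epoch_len, labels = hyp$labels,
            changed_from = changed, sleep_onset_epoch = onset)
}
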