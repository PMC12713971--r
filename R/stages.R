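#' Stage vocabularies
#'
#' Spectral scoring uses five stages named after the frequency band that
#' dominates each: `WAKE` (gamma, 40-95 Hz), `REM` (low beta, ~17-26 Hz),
#' `LIGHT` (sleep spindles, ~11-15.5 Hz), `HIDEEP` (delta, 1-3 Hz) and
#' `LODEEP` (slow oscillations, 0.1-1 Hz). Visual (AASM) hypnograms used as
#' comparison references carry the conventional vocabulary `wake`, `N1`,
#' `N2`, `N3`, `REM`.
#'
#' The order of `SPECTRAL_STAGES` is also the tie-break order used by
#' posterior decoding: when two stages have exactly equal posterior
#' probability the one listed first wins.
#'
#' @format Character vectors of stage labels.
#' @export
SPECTRAL_STAGES <- c("WAKE", "REM", "LIGHT", "HIDEEP", "LODEEP")

#' @rdname SPECTRAL_STAGES
#' @export
VISUAL_STAGES <- c("wake", "N1", "N2", "N3", "REM")

# stages whose band feature is dominated by sub-spindle frequencies
.DEEP_STAGES <- c("HIDEEP", "LODEEP")
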