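# specscore

Spectral sleep scoring of single-channel forehead EEG in R.

## The problem

Conventional sleep staging is visual: technicians page through a night of
polysomnography in 30-s epochs and assign AASM stages (wake, N1, N2, N3,
REM). It is expensive, slow, variable between scorers, and blind to a
physiological distinction that is obvious in any whole-night spectrogram:
deep sleep comes in two spectrally distinct flavours, a delta-dominated
state (1-3 Hz) and a slow-oscillation-dominated state (< 1 Hz).

`specscore` implements the alternative: let the spectrum define the
stages. One channel of forehead EEG is decomposed into a whole-night
time-frequency representation, and each 30-s epoch is summarised by five
band powers that each characterise a stage:

| Stage  | Band        | Rhythm |
|--------|-------------|--------|
| Wake   | 40-95 Hz    | gamma |
| REM    | ~17-26 Hz   | low beta |
| Light  | ~11-15.5 Hz | sleep spindles |
| Hi Deep| 1-3 Hz      | delta |
| Lo Deep| 0.1-1 Hz    | slow oscillations |

The output is both a hypnogram and the spectrogram it came from, so the
scoring can be verified by eye — something no black-box classifier
offers.

## The method

1. **Morlet wavelet spectrogram.** 100 log-spaced frequencies on
   0.1-100 Hz, 3 cycles at the lowest frequency grading to 30 at the
   highest, power at 0.5-s steps, converted to dB.
2. **Baseline removal.** Noise bins (extreme RMS or total power) are
   detected and excluded; the per-frequency whole-night mean is
   subtracted, leaving relative dB. Line noise (50-70 Hz) is masked for
   display and excluded from the Wake band.
3. **Band features.** Mean relative dB per epoch in the five bands.
4. **HMM staging.** A five-state Gaussian-emission hidden Markov model
   is initialized from per-epoch argmax band labels, refined by
   Baum-Welch EM, and decoded by *maximal posterior probability* per
   epoch (forward-backward, not Viterbi).
5. **Peak refinement.** Spindle and REM-beta peak frequencies are found
   from the first pass; the Light band becomes `[peak-1, peak+1.5]` Hz
   and the REM band `[peak-2, peak+2]` Hz, and the night is re-scored.
6. **Corrections.** Four rules repair characteristic mis-scorings
   (e.g. Wake with clear sleep rhythms after sleep onset becomes NREM),
   each correction marked per epoch.

Hypnogram comparison tools (confusion matrices, row/column percentages,
cross-subject medians, stage durations) and a synthetic sleep-EEG
generator with known ground truth round out the package.

## Worked example

```r
library(specscore)

# a synthetic 8-h night with known stages: 5 sleep cycles of
# Light -> Hi Deep -> Lo Deep -> Light -> REM between wake bouts
night <- generate_night(make_cycle_script(seed = 1))
scored <- score_recording(night$recording)
scored
#> <sleep_scoring> channel FP1-AFz
#> <hypnogram> 960 epochs x 30 s (WAKE:60 REM:200 LIGHT:350 HIDEEP:150 LODEEP:200)
#> hours: WAKE 0.50, REM 1.67, LIGHT 2.92, HIDEEP 1.25, LODEEP 1.67

# agreement with the generator's ground truth
mean(scored$hypnogram$stages == night$hypnogram$stages)
#> [1] 1

cm <- confusion(night$hypnogram, scored$hypnogram)
percentize(cm, "rows")["HIDEEP", c("HIDEEP", "LODEEP")]
#> HIDEEP LODEEP
#>    100      0

render_report(scored, "report.png", ref_hyp = night$hypnogram)
```

The printed hours are exactly the script's stage budget (0.5 h wake, 5
cycles x 20 min REM, etc.), and on this clean synthetic night every
epoch is recovered, including the delta vs slow-oscillation split of
deep sleep that visual scoring collapses into N3.

Real recordings enter through EDF:

```r
rec <- derive_third_channel(read_edf("night.edf"))  # adds FP2-AFz
scored <- score_recording(rec, "FP1-AFz")
write_hypnogram(scored$hypnogram, "hyp.csv")
```

A thin command-line wrapper lives in `inst/cli/specscore.R`
(`score`, `simulate`, `compare` subcommands).

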