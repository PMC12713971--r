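---
title: "Spectral sleep scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral sleep scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specscore)
```

This vignette is the package's account of its science: what the model
is, what the tunable parameters mean, what the synthetic generator does
and does not emulate, and where the design was genuinely open and a
choice had to be made.

## The staging model

Sleep staging here is not a reconstruction of what a human scorer would
see in the time domain. The spectral stages are *defined* by which of
five frequency bands dominates an epoch's spectrum: gamma (40-95 Hz)
for Wake, low beta (~17-26 Hz) for REM, the spindle band (~11-15.5 Hz)
for Light, delta (1-3 Hz) for Hi Deep, and slow oscillations (0.1-1 Hz)
for Lo Deep. The last two both correspond roughly to visual N3; keeping
them separate is the point — delta and slow oscillations have different
cortical/thalamic origins and different behavioural correlates, and a
whole-night spectrogram shows them as plainly distinct states.

The pipeline is:

1. raw EEG → Morlet wavelet spectrogram (dB),
2. noise-bin detection → whole-night baseline subtraction (relative dB),
3. per-epoch five-band features,
4. five-state Gaussian-emission HMM: argmax initialization, Baum-Welch
   EM, maximal-posterior decoding,
5. spindle/REM peak refinement and a second pass,
6. rule-based post-HMM corrections.

## Time-frequency decomposition

The wavelet bank uses 100 log-spaced frequencies on [0.1, 100] Hz. The
frequency range is prescribed by the band definitions; the *resolution*
is a package choice: 100 points give ~33 points per decade, about 7%
spacing, comfortably finer than any band (the narrowest, Light, spans
~0.15 decades ≈ 5 grid rows) while keeping the whole-night matrix
(57,600 bins × 100 rows for 8 h) small enough to hold in memory
alongside its copies.

Cycles per wavelet grow linearly in log10(frequency) from 3 at 0.1 Hz
to 30 at 100 Hz. Linear-in-log-frequency is the simplest smooth
monotone rule through both endpoints, and it keeps the time support
(≈ cycles/frequency) from exploding at the slow end: 3 cycles at
0.1 Hz is a ±19 s effective support, already the dominant edge effect.

The transform itself is a Morlet filter bank evaluated in the frequency
domain: one FFT of the zero-padded record, then for each grid frequency
the spectrum is multiplied by the wavelet's Gaussian frequency response
(standard deviation f/cycles) and inverted by a short FFT over just
that band at a reduced sampling rate aligned with the 0.5-s hop. This
is mathematically the same convolution as a time-domain implementation
but runs in seconds on a full night in interpreted R, and sampling the
band signal at hop centres makes the result *exactly* shift-equivariant
for delays that are whole hops — a property we test. Two numerical
consequences are worth knowing:

* Power is floored at 1e-12 (µV²-scale units) before the log, so
  silence maps to a finite −120 dB. dB values within ~40 dB of the
  floor describe sub-numerical amplitudes; differences there are not
  meaningful, and tests avoid asserting on them.
* For broadband signals, shift equivariance holds to ~3e-3 dB rather
  than machine precision: delaying a *finite* record is not a pure
  shift for frequency content with periods comparable to the record
  length, which the 0.1-0.3 Hz wavelets can see. This is windowing
  physics, not implementation error.

The quoted dB convention ("multiplying the complex number by its
conjugate") logs the squared magnitude: dB = 10·log10(power). Whether
the original formula logged amplitude or power is ambiguous in the
source description; power is the default and `db_mode = "amplitude"`
(5·log10(power), i.e. half the scale) is exposed in the config. The
choice only rescales every feature and threshold jointly, so staging is
unaffected apart from the correction thresholds' units.

Edge bins — where the longest wavelet (±4σ ≈ ±19 s) extends past the
record — are computed against implicit zeros and flagged in
`edge_bins`; downstream the noise detector ignores their spectral
feature so start-up transients are not mistaken for artifacts.

## Noise detection and baselining

The baseline is the per-frequency mean dB over the night excluding
noise bins; subtracting it expresses everything as "dB relative to this
night's typical spectrum", which is what makes thresholds transferable
across recordings and gains.

Noise bins are found from two features: the 2-s windowed RMS of the raw
signal (in dB) and each bin's mean dB across the frequency grid. A bin
is flagged when either deviates from the night *median* by more than
`z_thresh = 4` standard deviations. The centre is robust (an artifact
span cannot drag the median) but the scale deliberately is not: the SD
is inflated by the night's physiological stage variation, so
high-amplitude slow-wave sleep — routinely 4-6× the night-median RMS,
which a MAD-scaled score at any conventional threshold would flag
wholesale — stays inside the fence, while broadband excursions like a
×20 gain artifact (+26 dB) are far outside it. A feature with less
than 0.5 dB of spread marks a stationary record (warning, no flags):
genuine artifacts are tens-of-dB excursions, and sub-dB ripple must not
masquerade as outliers.

Whether detection should operate on 0.5-s bins or whole epochs was
open; it operates on bins (the mask is reused bin-wise by the baseline
and display), and epochs inherit a flag when ≥ 50% of their bins are
masked.

## Band features and epoching

Epochs are 30 s by default (a trailing partial epoch is dropped);
anything down to ~10 s remains usable, below which momentary spindle or
delta bursts flip dominance and the hypnogram churns. Features are
plain means of relative dB over each band's grid rows and the epoch's
bins — deliberately unsmoothed: the 40-s moving average exists for the
*display* spectrogram and the dominant-frequency trace only, because
scoring features already average 60 bins per epoch and extra smoothing
would blur stage transitions. The Wake band skips the 50-70 Hz rows
(mains interference and its spread); the display interpolates across
them in log-frequency. Band edges are treated as closed intervals; the
shared 1 Hz grid point between Hi and Lo Deep contributes to both,
which is immaterial against their 2-decade-wide separation in content.

## HMM staging

Emissions are diagonal-covariance Gaussians over the five features. The
emission family is not prescribed by the band-dominance idea itself; dB
features are close to Gaussian within a stage, and with only a few
hundred epochs per stage per night, full covariances or mixtures make
EM fragile for no visible gain. Variances are floored at 0.25 dB² so a
nearly-constant synthetic stage cannot collapse a Gaussian.

Initialization labels each epoch by its argmax band (band k ↔ stage
k) — on well-separated nights this is already nearly the answer — and
moments, transition counts (plus `sticky = 5` diagonal pseudo-counts
and a 0.1 uniform smoothing so no transition starts impossible) and a
Wake-heavy initial distribution (`pi_wake = 0.6`; nights start awake)
follow from those labels. EM runs at most 50 iterations or to a
relative log-likelihood improvement below 1e-6; whether the original
method iterates to convergence is unstated, so both knobs are config.
The default initialization is deterministic, so the pipeline is
bit-reproducible; no random restarts are used.

Decoding assigns each epoch the stage with maximal conditional
probability from scaled forward-backward — the per-epoch marginal, not
the Viterbi path. The distinction matters at ambiguous epochs inside
stable runs, and a test constructs a fixture where the two disagree to
pin the implemented rule. Ties resolve by the fixed stage order Wake >
REM > Light > Hi Deep > Lo Deep. Epochs flagged as noise are treated
as *unobserved* in the emission model (likelihood 1 for every stage):
they are still decoded from context, contribute nothing to EM emission
statistics, and — because this is exact missing-data EM — the
likelihood guarantee (monotone, checked to 1e-9 each iteration)
survives masking.

## Peak refinement

Spindle and REM-beta frequencies differ between sleepers. After the
first pass, the mean first-pass-Light spectrum is searched for its peak
in 9-16 Hz and the Light band re-centred to [peak−1, peak+1.5] Hz;
likewise REM in 15-30 Hz to [peak±2] Hz. The search windows are a
package choice (the offsets around the peaks are given, the windows are
not): 9-16 Hz brackets the physiological spindle range, 15-30 Hz the
low-beta REM rhythm, and both exclude each other's peaks. The second
pass re-fits the HMM on the refined features. A stage absent from the
first pass leaves its band at the default.

## Correction rules

Four per-epoch rules run in order after decoding; the first that
triggers changes the epoch once (single pass, no cascading), recording
the previous stage in `changed_from`:

1. Deep → REM (or Wake when the gamma band beats the beta band) when
   beta − spindle ≥ 2 dB and spindle power is below baseline.
2. Deep → Wake when the epoch's whole-spectrum mean is ≥ 15 dB above
   the night median and spindles are below baseline (broadband noise,
   not sleep).
3. Deep → Light when spindle power exceeds both low-frequency bands.
4. Wake → Hi Deep or Light (whichever band is stronger) when delta or
   spindle power is ≥ 2 dB above baseline — only after sleep onset,
   defined as the first run of ≥ 10 consecutive non-Wake epochs
   (5 min), so pre-sleep wakefulness is never converted. This rule also
   restores gamma-contaminated sleep that the HMM pulled to Wake.

The rule logic is prescribed; the thresholds are not, so they are
expressed on the relative-dB scale (hence transferable) and exposed in
config. The 15 dB fence in rule 2 deserves a note: an epoch's
whole-spectrum mean rises by ~5-10 dB during genuine slow-wave sleep
simply because delta dominates a log-spaced grid, so a low fence would
convert clean deep sleep to Wake; the broadband artifacts the rule
targets sit far above +15 dB. Re-applying the corrections is a no-op by
construction: marked epochs are skipped and the onset index is reused,
which is what makes "corrections are idempotent" a testable contract.
On clean, well-separated nights no rule should fire at all, and the
synthetic end-to-end tests confirm zero or near-zero corrections.

## The synthetic generator

`generate_night()` builds 1/f (exponent 1.0) pink noise at 10 µV RMS
and adds per-segment stage signatures: broadband 40-95 Hz gamma at
3 µV for Wake, a narrow ~20 Hz rhythm at 5 µV for REM, 13 Hz spindles
as 1-s Hann bursts every 4-6 s (jittered) at 8 µV for Light — bursty
rather than continuous, as in physiology, which stresses the epoch
averaging — 1-3 Hz delta at 40 µV for Hi Deep, and 0.4-0.9 Hz slow
oscillations at 60 µV plus mild (3 µV) spindle content for Lo Deep,
mirroring the coexistence of K-complex/spindle activity in deep sleep.
REM segments carry no spindles. Amplitudes were chosen once to give
each stage unambiguous band dominance while overlapping realistically
with the background; they are script parameters, not tuning knobs.

What the generator does *not* emulate: eye movements, EMG and ECG
contamination, electrode pops, sweat artifacts, gradual impedance
drift, stage transitions inside an epoch, or the continuum of ambiguous
mixed epochs real sleep produces. Passing the end-to-end tests
therefore demonstrates that the pipeline's machinery is correct and
self-consistent — not that it reaches any particular agreement with
human scorers on clinical data, which can only be established against
real simultaneously-scored recordings.

## Problem sizes and determinism

The test suite and acceptance script run the full pipeline on five
seeded 8-h nights at 500 Hz (960 epochs each) — the canonical cycle
structure Wake → (Light, Hi Deep, Lo Deep, Light, REM)×5 → Wake — plus
shorter 2-h fixtures for module tests; these sizes exercise every code
path at full night scale while keeping a complete run in minutes. All
randomness flows through explicit seeds: the same seed reproduces a
generated night bit for bit, and scoring itself contains no randomness
at all.

## Known limitations

* Single-channel scoring by design; multi-channel nights are scored
  channel by channel.
* Frontal theta is not used for REM (too inconsistent frontally), and
  alpha is not used for Wake (weak at the forehead); gamma and low
  beta carry those stages instead.
* EDF support covers continuous, equal-rate records (the forehead-patch
  case), not EDF+ annotations or discontinuous files.
* Epoch alignment between hypnograms is by index from a common start;
  sub-epoch offsets between simultaneously recorded devices are out of
  scope.
* N1 has no spectral equivalent; comparisons against visual scoring
  keep the N1 row and simply show where those epochs land.
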