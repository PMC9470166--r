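---
title: "Drinking microstructure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drinking microstructure: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipstruct)
```

This vignette is the package's account of the science behind each stage:
what is being modelled, which knobs matter, and where the design was
genuinely open and a choice had to be made.

## The device model

A lickometer samples an infrared beam continuously but commits to memory at
minimum every 2 s. The observable record is therefore not the lick stream
but *bouts*: clusters of licks with a lick count and a total beam-broken
time ("lick duration"). Two facts pin the emulation down: any tube
interaction within a 2 s window belongs to one bout, and bouts can be longer
than 2 s but never shorter.

The written record does not say whether the 2 s window is anchored at bout
onset or acts as a maximum inter-lick gap. `device_emulate()` implements the
gap reading: a bout closes when more than `gap` seconds (default 2.0) elapse
after the previous lick's *onset*, and the recorded span is floored at
`gap`. This is the only reading that reproduces the "never shorter" rule for
a solitary lick (one 0.1 s lick still yields a 2 s bout) without inventing
firmware behavior. `gap` is exposed as a parameter rather than hard-coded,
since the physical device's write clock is unknown.

Times are decimal seconds from session start; lick events are half-open
intervals `[onset, offset)`, so an onset exactly at the previous offset is
legal contact chatter, not an overlap.

## Cleaning by the licks-versus-duration line

Genuine licking ties the number of licks in a bout linearly to the bout's
beam-broken time (each tongue contact blocks the beam for a roughly constant
interval, so the slope is about one over the mean contact time — near
20 licks/s for ~50 ms contacts). Slow leaks block the beam for seconds with
almost no licks; chews produce dozens of sub-10 ms contacts. Cleaning fits
`n_licks ~ lick_duration` by ordinary least squares and removes bouts with
|residual| > 3 (lick units), in a single pass — no refitting after removal.

Two consequences worth knowing:

* **The fit is deliberately not robust.** With sparse contamination (real
  rates are on the order of 0.03% of bouts) the OLS line is essentially the
  drinking line and removal is near-perfect (sensitivity and specificity
  above 0.95 in the tests at ~0.6% planted contamination, about 17 times
  the realistic rate). At several percent of high-leverage contamination the
  line itself is dragged and specificity collapses. Robust variants are out
  of scope by design; the procedure is the plain OLS + cutoff.
* **Grouping.** The default is one global fit pooled over all bouts, which
  matches reporting a single retention figure; `grouping = "per_animal"`
  fits per animal and skips degenerate groups (fewer than 2 bouts, or all
  durations equal) with a warning.

## The 18-feature registry

The canonical per-session feature vector (`feature_registry()`) holds
totals (licks, lick duration, bouts), per-bout means, per-bout maxima,
latency to drink (first lick onset), mean and max inter-drink interval,
the first-30-minute totals (front-loading), per-minute rates, and
`front_loading_index = bouts_first_30min / max(total_bouts, 1)`. Eight of
these are standard named microstructure measures; the remaining ten complete
the set with the natural totals/means/maxima/rates family. The registry is a
fixed ordered vector so the classifier's input layout is stable; alternative
sets would be drop-in replacements.

Decisions embedded in the definitions:

* **Inter-drink interval** runs from a bout's *end* to the next bout's
  *start* ("time between bouts" is ambiguous between onset-to-onset and
  end-to-start; end-to-start measures the pause during which the animal is
  not drinking).
* **First 30 minutes** membership is by bout start < 1800 s. A bout starting
  at 2000 s is outside the window regardless of how the arithmetic in an
  informal example might be rounded.
* **Imputation** keeps the feature matrix rectangular: a session with no
  bouts has zero totals/maxima/rates and latency and both inter-drink
  intervals censored at the session length in seconds (a "no second drink"
  value); a single-bout session censors the inter-drink intervals the same
  way. Dropping such sessions would bias the classifier against the very
  manipulations that suppress drinking.
* **Dose is not a feature.** The registry is microstructure only; g/kg
  intake is computed separately (`compute_intake()`) with configurable
  densities (water 1.000, 20% v/v solution 0.970, ethanol 0.789 g/ml) and
  used for the intake-correlation checks and the inclusion filter.
* **Inclusion** ("outside the lower interquartile range") is implemented as
  the Tukey lower fence Q1 − 1.5·IQR with linear-interpolation (type 7)
  quantiles, per fluid group, which reproduces excluding a near-zero drinker
  while keeping ordinary variation.

## The classifier

Features are concatenated across animals and sessions, labels are the
one-hot fluid × virus product (water:ChR2, water:eGFP, alcohol:ChR2,
alcohol:eGFP), and columns are min-max normalized to [0, 1] *on the full
dataset before cross-validation* — replicated as the default for fidelity to
the modelled workflow, with `fold_safe = TRUE` fitting scalers on training
folds only for users who want to avoid the (mild) leakage of per-column
ranges.

`stratified_kfold()` shuffles each class independently under the seed and
deals members across folds as evenly as possible, with remainders going to
the least-filled folds. On a 998-row table with class sizes 240/278/240/240
this yields test folds of 167, 167, 166, 166, 166, 166 — the modal 166-row
test fold implies 832 training rows. Classes smaller than k warn and occupy
a subset of folds; the hard errors are k < 2 and k exceeding the row count.

The network is a sequential dense ReLU stack with a softmax output, trained
with Adam (step size 1e-3) on categorical cross-entropy, one freshly
initialized network per fold (He-scaled Gaussian init, seeded per fold).
The reference architecture is 2048-512-64-4; epochs (100) and batch size
(32) are defaults, as they are not pinned by the modelled workflow. The
implementation is a from-scratch matrix MLP so the package trains and tests
without any deep-learning framework; argmax ties resolve to the lowest
class index, deterministically. *Chance* is reported as the modal-class
frequency — the accuracy of always guessing the most common label, which is
the honest baseline for unbalanced classes — with the uniform 1/4
alternative alongside.

For simulation-scale work (tests, the acceptance script, `run_pipeline()`
defaults) a reduced 128-64-32-4 network at 30–40 epochs is used on cohorts
of roughly 80–1050 sessions; at these problem sizes the reduced network is
already past its accuracy plateau on the synthetic task, and the
architecture is a `network_spec()` parameter throughout.

## The synthetic cohort generator

`generate_cohort()` emulates the study structure: four fluid × virus
classes (defaults 8/11/8/8 animals), six drinking weeks of five sessions
(four 2 h, one 4 h), per-animal body weights and bottle weights. Within a
session:

* latency to first bout is log-normal (median 240 s, sdlog 0.5);
* bouts are a renewal process with gamma inter-bout gaps (shape 1.5, mean
  300 s, measured bout end to next bout start), with gaps divided by a
  front-loading boost (1.8) during the first 30 min;
* bout lick content comes from a log-normal active-licking duration
  (median 4 s) at a 7 Hz within-bout lick rate — a typical mouse licking
  rhythm — with ~50 ms tongue contacts jittered ±15% so the
  licks-versus-duration relation is tight but not degenerate;
* rare leak and chew event clusters (each 1% of sessions by default; the
  realistic order of magnitude) are inserted into quiet parts of the
  stream, carrying the long-duration/few-licks and many-licks/short-duration
  signatures that give them |OLS residual| ≫ 3;
* the bottle loses mass as a noisy (5% CV) monotone function of the true
  drinking lick duration, converted through the fluid density, so intake
  correlates with the lickometer totals as it does in practice (r > 0.9).

Class structure enters as multiplicative effects on the gap mean, bout
duration, front-loading boost and latency: alcohol drinkers front-load more
and take longer bouts; the water opsin group has a modest baseline offset;
and the alcohol-opsin class acquires a week 5–6 deficit (−30% bouts and
licks, −40% front-loading) emulating closed-loop photoexcitation during the
evaluation weeks. These magnitudes are free parameters — the directions and
week-specificity mirror the modelled study, the sizes are chosen to be
plausible, and `effect_scale` exponentiates all of them: 0 collapses every
class onto the shared baseline (classifier at chance), larger values
separate the classes monotonically.

Randomness is organized as one cohort seed with a derived substream per
animal, so adding an animal to a class never perturbs the sessions of
existing animals. Ground truth (event streams, drawn latencies and gaps,
contamination flags, resolved per-session parameters) is returned alongside
the sessions, and the distribution-recovery tests read the drawn values from
it rather than re-deriving them through censored session views.

What the generator does *not* emulate: pharmacokinetics (no blood-alcohol
model), circadian structure within sessions beyond the front-loading boost,
bout-duration/interval autocorrelation, device clock quantization, or
session-to-session learning. Passing tests therefore demonstrate the
pipeline's correctness and sensitivity on a faithful-but-idealized
behavioral process, not performance on any particular real dataset — real
recordings' class separability and contamination structure can differ
substantially.

## Electrophysiology measurements

Synthetic sweeps are difference-of-exponential synaptic waveforms plus
Gaussian noise at 10 kHz; emitted waveforms are normalized so the *sampled*
peak equals the configured amplitude exactly, which makes noiseless
recoveries exact rather than off by sub-sample peak interpolation.

* **Evoked amplitude** = |extremum in a post-stimulus search window −
  pre-stimulus baseline mean|. The search window defaults to 2–50 ms and
  the baseline to the 50 ms before the stimulus (both configurable; neither
  is pinned by the modelled protocol). Inward currents are negative;
  amplitudes are reported as positive magnitudes.
* **AMPA/NMDA**: AMPA is the evoked peak at −80 mV (peak, not windowed
  mean — the estimator is configurable in the window arguments, and peak is
  the conventional choice); NMDA is the baseline-subtracted mean current
  100–125 ms post-stimulus at +40 mV, where the fast component has fully
  decayed. If the window mean does not clear a noise floor (3 standard
  errors of the baseline), the ratio is flagged undefined instead of
  returning a meaningless number.
* **Paired-pulse ratio**: first-pulse amplitudes against the pre-stimulus
  baseline, second-pulse amplitudes against the tail current in the 5 ms
  before the second stimulus, ratio of the replicate means (1–3 replicates).
  The tail baseline removes most of the first pulse's decay; the residual
  bias is the decay's change between the tail window and the second peak,
  under 1% for ISI ≥ 100 ms at realistic decay constants.
* **Population spikes** default to baseline-to-negative-peak (the
  measurement geometry is a convention, so `peak_to_peak` is available).
* **sEPSC detection** is a plain amplitude-threshold detector with 2 ms
  refractory merging — a transparent stand-in for commercial event software,
  not a clone. Amplitude is measured against a local pre-onset baseline
  separated from the crossing by 3 ms so the event's own rise does not bias
  it. Decay tau is a single-exponential fit starting below 85% of the peak
  (past the rising-phase mixture) with a log-linear fallback. Because the
  underlying events are difference-of-exponentials, the single-exponential
  tau is intrinsically biased high, and the bias grows with noise (about
  +4% at 1 pA noise, +11% at 1.5 pA for 5 ms events); tests assert ±0.5 ms
  recovery at noise ≤ 1 pA and ±1 ms at the noisier default.
* **QC**: exclude a cell when series resistance exceeds 25 MΩ at either end
  of the recording or drifts more than 15% of its starting value.

## Numerical and reproducibility choices

CSV round-trips are bit-exact: writes use the shortest round-trip decimal
representation and reads parse with strtod (base `read.csv`), which is
correctly rounded. All simulation entry points take seeds and restore the
caller's RNG state; the pipeline manifest hashes the canonical
(recursively name-sorted) JSON of the configuration, so semantically equal
configs hash equal regardless of field order. Degenerate inputs error with
the offending field named; pipeline stage failures name the stage and leave
earlier stages' outputs on disk.

## Known limitations

* The cleaning step inherits OLS's sensitivity to dense high-leverage
  contamination (by design, see above).
* Per-event sEPSC decay constants carry the documented noise-dependent
  upward bias; averaging event waveforms before fitting would reduce it but
  changes the reported quantity.
* The classifier's default normalize-then-split ordering leaks per-column
  ranges across folds; it is kept as the default deliberately (with
  `fold_safe` provided) because it reproduces the modelled analysis.
* Generator effect sizes are plausible free parameters, not fitted values;
  absolute accuracies on synthetic cohorts are properties of those choices.
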