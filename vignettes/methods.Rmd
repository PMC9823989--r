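---
title: "Sleep staging and sleep-quality classification from RR intervals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging and sleep-quality classification from RR intervals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiosleep)
```

## The problem

Polysomnography is the clinical reference for sleep staging, but it is
intrusive and impractical for routine monitoring. A single-lead chest ECG (or
any device yielding the cardiac cycle sequence) is far easier to wear through
the night. Heart rate and heart rate variability (HRV) are modulated by
autonomic state, which in turn tracks sleep depth: sympathetic activation in
wakefulness and REM, parasympathetic dominance with strong respiratory sinus
arrhythmia in deep sleep. `cardiosleep` implements a two-step analysis of a
night of RR intervals:

1. **Staging** — classify every 30-s epoch as wake (W), REM (R), light sleep
   (L = N1+N2) or deep sleep (D = N3), using per-stage *recognizers* built
   from smoothed principal-component curves of small HRV feature sets, plus a
   probabilistic fusion step that resolves conflicting recognizer tags with
   three Platt-calibrated SVMs.
2. **Quality** — summarize the resulting hypnogram into night-structure
   features (efficiency, fragmentation, transition intensity, stage
   durations) and classify the night as *good* or *poor* sleep with a
   third-order polynomial SVM, against a questionnaire-derived label
   (score 0–22; good is a score of at most 6).

## Preprocessing

R peaks are detected with the classic band-pass / derivative / squaring /
moving-window-integration detector (5–15 Hz band, 150 ms integration,
adaptive dual thresholds, 200 ms refractory period). Beats are then screened:
intervals above 2 s or below 0.35 s are invalid, as are "irregular" beats
deviating more than 20% from the median of the five surrounding plausible
intervals — a standard ectopic-beat heuristic; the exact rule is
configurable because the literature leaves it open. Invalid beats are
*flagged*, never removed or interpolated; time-domain statistics skip them
(and any successive difference spanning them), while spectral features bridge
them implicitly through the resampling spline.

If a recording opens with more than five minutes of wake, everything before
the final five wake minutes is discarded. Records are excluded wholesale when
shorter than 5 h, when the apnea–hypopnea index is 5 or more, when objective
sleep efficiency is below 75%, when more than 45 min of leading or 30 min of
trailing wake remain, or when more than a quarter of the signal is noise.
Sleep efficiency for screening is computed between the first and last
non-wake epoch, since the term is otherwise undefined for an open-ended
recording.

Every epoch is analysed on the 4 min 30 s of signal centered on it (nine
epochs). In training mode, windows truncated at the record edge or spanning
more than two distinct annotated stages are dropped; at inference every epoch
is scored.

## Features

Per window the package computes 23 HRV candidates: time-domain (HR, SDNN,
RMSSD, SDSD, PNN50), spectral (VLF, LF, HF, LF/HF, LFn, HFn on the 4-Hz
spline-resampled tachogram, Welch spectrum with 128-s Hann segments at 50%
overlap), respiratory (resf — the dominant tachogram frequency in
0.15–0.5 Hz; strf — the SD of resf over five 90-s sub-windows; coRR — the
correlation of the interval sequence with its twice 3-point-smoothed
version), detrended fluctuation analysis (alpha1 = slope, alpha2 = offset of
the log–log fit over scales 4–64 beats; a conventional dual-exponent variant
is available behind a flag), sample and fuzzy entropy (m = 2, r = 0.2 SD),
Poincaré SD1/SD2, the time-irreversibility statistics P1 and G1 on the signs
and energies of successive differences, and corr2, the lag-2
self-correlation. Thirteen of these survive the useless-feature elimination
(HR, PNN50, LF, LF/HF, coRR, resf, strf, alpha1, alpha2, SE, P1, G1, corr2);
all 23 remain computable for the selection machinery.

Twenty *contextual* features relate each epoch to its neighbourhood: slopes
between the first/second maxima and minima of the 3-point-smoothed HR and
respiratory-rate courses in the 3-min windows before (`a` prefix) and after
(`z` prefix) the epoch, and ratios of the epoch's HR and respiratory rate to
their centered one-hour and overnight means. The per-epoch "instantaneous"
HR and respiratory-rate series are the window HR and resf values, one per
epoch.

Numerical conventions worth stating:

* Poincaré axes use population second moments with SD1 measured about the
  line of identity, so `SD1 = RMSSD / sqrt(2)` holds exactly — the two
  common textbook definitions only coincide under this convention.
* Sample entropy of a constant window is 0 by convention; windows where no
  template pair matches yield a missing value rather than infinity.
* Welch spectra are computed by a small internal routine (Hann window,
  mean removal per segment, one-sided folding); no installed package
  offers a Welch estimator.
* Every feature is either finite or an explicit `NA`; downstream consumers
  impute by night medians (curves) or training medians (classifiers) and
  log nothing silently.

## The staging model

For each stage a *recognizer* holds a small feature combination (defaults:
W = coRR, HR, resf, alpha2; R = coRR, HR, resf, alpha1, alpha2, G1;
L = HR, resf, SE, alpha2, P1; D = resf, LF, alpha1, corr2). SE and alpha2
run counter to the other features across the night and are negated before
the PCA. Within each night the selected columns are z-scored, projected on
their first principal component (sign fixed so the first listed feature
loads positively — the component sign is otherwise arbitrary while the
detection criteria are one-sided), standardized, and smoothed twice with
Savitzky–Golay filters: a small frame `SF1` (default 11 epochs, ~5.5 min,
order 2) tracking epoch-scale variation and a large frame `BF1` (default
121 epochs, ~1 h) tracking the sleep-cycle scale. The frame lengths are free
parameters of this package; the defaults were chosen so the small frame follows
individual epochs and the large frame spans a full non-REM/REM cycle, and
both are configurable.

Detection criteria: `SF1 > BF1 + k` tags wake and REM epochs,
`SF1 < BF1 + k` tags deep sleep, and `BF1 + k1 < SF1 < BF1 + k2` tags light
sleep. Offsets are fitted per recognizer on training nights by grid search
(41 values over [-2, 2] component units; all pairs of a 15-point grid for
the light-sleep band), maximizing the mean of accuracy and Youden's index
(`sensitivity + specificity - 1`); ties resolve toward the smallest |k|.

**Boundary correction.** Epochs near a crossing of `SF1` and the offset
threshold are the likeliest errors. For every excursion beyond the threshold
the package finds the flanking minima and the excursion maximum, and ramps
the threshold on the medial side of each crossing: ramp height
`c_h * (H - L)` and width `c_w * (H - L) / |slope|` epochs (defaults
`c_h = 0.25`, `c_w = 0.5`; the proportionality constants are free
parameters and configurable). The threshold is raised
for W/R, lowered for D, and the band recognizer is left alone. Setting
`c_h = 0` disables the correction exactly.

**Fusion.** Each epoch ends up with zero to four tags. Three binary SVMs
(RBF kernel; features selected per classifier by linear SVM-RFE from the 13
retained HRV plus 20 contextual features; hyperparameters by a small inner
grid search; training rows capped at 3000 by stratified subsampling) are
Platt-calibrated on cross-validated margins: WR/N separates wake-or-REM from
NREM, W/R and L/D resolve within the groups. Routing follows the tag count:
one tag stands; tags {W,R} or {L,D} are resolved by the conditional
classifier alone (the group probability is deliberately not computed); one
tag from each group lets the WR/N classifier pick the group whose tag then
wins; zero, three or four tags fall through to the arg-max of the four joint
products P(WR)P(W|WR), P(WR)P(R|WR), P(N)P(L|N), P(N)P(D|N). Platt's
sigmoid is fitted with regularized targets so separable training folds do
not blow up the calibration.

**Post-hoc correction.** REM scored within the first 80 min after sleep
onset becomes wake; deep sleep within 30 min of the final awakening becomes
light sleep. Sleep onset is defined here as the first light- or deep-sleep
epoch: defining it as the first non-wake epoch would let the REM correction
move the onset itself, making the operation non-idempotent; with the L/D
definition applying the correction twice is exactly applying it once. The
final awakening only exists when the record ends in wake (the start of that
terminal wake run).

**Feature selection.** The exhaustive search over feature combinations of
size at most 3 builds a provisional recognizer per combination (PCA,
smoothing, best offset on the grid) and ranks by the accuracy/Youden mean.
Per stage, features present among the bottom quarter of combinations but
absent from the top quarter are "useless"; features useless for all four
stages are removed globally. The quarter fractions are configurable; the rule itself is a qualitative
heuristic and documented as such.

## The quality model

From a (predicted) hypnogram the package computes: sleep efficiency
(non-wake fraction of all epochs), total sleep time, the number of maximal
wake bouts after sleep onset, the transition intensity, the per-hour
frequency of W/R epochs beyond 6 h (missing for shorter records), NREM and
wake durations, REM and deep proportions, plus auxiliary candidates (sleep
and REM latencies, per-stage durations/proportions). Sleep onset here is the
first non-wake epoch. The transition intensity maps W, R, L/D to 1, 0, 1 and
sums absolute differences of neighbouring epochs — implemented verbatim,
although under this labelling wake/NREM changes are invisible; a signed
variant (1, 0, -1) is available behind a flag since the printed rule may be
a typo. The occurrence number of successive wake stages and "wakefulness
times" coincide under these definitions, so the feature table carries the
quantity once (`n_W_bouts`).

The classifier is a third-order polynomial-kernel SVM (`coef0 = 1`) on
standardized features, with the cost constant chosen by an inner grid
search, reported with 5-fold cross-validation (per-class accuracy, average
accuracy, macro F1). Scores of 6 or less are "good", above 6 "poor".

## The synthetic-data generator

No public RR database ships with this package; instead a generator produces
fully specified nights so every component is testable end to end.

* **Hypnograms** follow a semi-Markov chain: geometric bout lengths with
  per-stage means (W 2, R 15, L 25, D 12 min; a 10-min opening wake bout)
  and transition weights that produce the cyclic L–D–L–R structure of
  healthy sleep at roughly the conventional 90-min period, with brief
  awakenings.
* **RR series** are generated beat by beat: a stage-dependent baseline
  (W 800, R 850, L 950, D 1020 ms), a 0.1-Hz low-frequency sinusoid, a
  respiratory sinusoid at the stage's breathing frequency (W 0.35, R 0.30,
  L 0.26, D 0.22 Hz) and Gaussian jitter (W 45 down to D 7 ms); 1% of beats
  are replaced by out-of-range artifacts to exercise the beat screening.
  The parameters encode the qualitative stage contrasts the staging method
  presumes — faster, more variable rhythm awake and in REM; slow, regular,
  respiration-dominated rhythm in deep sleep — and are documented defaults,
  not claims about physiology.
* **Cohorts** plant a good/poor label per subject (35% poor by default) and
  bias poor nights toward more and longer awakenings (wake transition
  weight x4, wake bouts x2, opening wake x3) and fragmented REM (REM bouts
  x0.4, transitions into REM x3). The REM fragmentation is what raises the
  transition intensity under the printed 1/0/1 labelling, which only sees
  REM entries and exits; inflating wake transitions alone would actually
  lower it. A consistent questionnaire score (good 0–6, poor 7–14) is
  drawn per subject.

What the generator does *not* emulate: apnea events, arrhythmias, real QRS
morphology (the synthetic ECG is a stereotyped template train for testing
peak detection), circadian drift within stages, and inter-subject baseline
variability beyond the stage parameters. Passing end-to-end tests therefore
demonstrates that the pipeline recovers structure *of the kind the method
assumes*, at realistic contrast — not clinical performance on real data:
cardiac-only four-class staging on large polysomnography databases is
typically reported around 0.6–0.7 accuracy, far below EEG-based staging.

## Problem sizes and experiment protocol

The bundled recovery experiment (`cohort_experiment()`) simulates 40
eight-hour nights, splits them in half at the subject level, trains the
recognizer offsets and fusion classifiers on the training half, stages the
test half, and trains/evaluates the quality model on features of the
*predicted* hypnograms. These sizes keep a full run in a few minutes of one
CPU while leaving ~19,000 training epochs for the fusion SVMs (subsampled to
3000 rows per classifier), and they are the defaults written into
`cohort_config()`. The acceptance script (`scripts/acceptance.R`) runs this
experiment plus the fast calibration checks (brute-force feature oracles,
DFA slopes on white noise and random walks, spectral recovery of planted
modulations, SVM-RFE planted-feature recovery, permuted-label nulls).

## Known limitations

* The staging model normalizes and fits its principal component per night;
  very short or structureless records (under ~an hour) give unstable curves.
* DFA reports slope and offset of a single fit by default, though the
  two-regime convention is more common in the HRV literature — hence the `dual_exponent` switch.
* The exact definitions of several source-method constants (smoothing
  frames, boundary-adjustment constants, the irregular-beat rule, the
  useless-feature thresholds) are not published; all are exposed in
  `default_config()` and documented above as this package's choices.
* Platt calibration on small classifier subsets (tens of nights) is noisy;
  probabilities should be read as rankings rather than frequencies at that
  scale.
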