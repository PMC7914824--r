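---
title: "Methods: neonatal phonocardiogram murmur screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal phonocardiogram murmur screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neopcg)
```

## The problem and the pipeline

Patent ductus arteriosus (PDA) and other congenital heart defects (CHD)
can imprint murmurs — band-limited noise from turbulent flow — on a
newborn's heart sounds. PDA typically produces a continuous murmur best
heard at the pulmonic auscultation point; many CHDs produce systolic
murmurs. `neopcg` turns digital-stethoscope recordings from the five
standard auscultation points into one per-patient probability through
four stages: (1) audio I/O and resampling to the 2 kHz analysis rate,
(2) extraction of 200 features per manually segmented heartbeat cycle,
(3) a gradient-boosted tree classifier with binary logistic loss, and
(4) aggregation of cycle-level information across cycles and points.
Segmentation itself is assumed given (cycles delimited into S1, systole
m1, S2, diastole m2); the package validates, persists, and rescales
annotations but does not create them.

## Audio handling

Recordings are mono 16-bit PCM WAV at any rate (clinically, 44.1 kHz).
Integer samples are divided by full scale (32768) on load; no gain
normalization is applied at I/O time so the representation stays
lossless — scale robustness is delegated to the dB-scaled features.
Resampling to 2 kHz (the highest analysed frequency is 1 kHz) applies a
zero-phase frequency-domain low-pass — unit gain below 0.40 of the
target rate, raised-cosine roll-off to zero at 0.50 — followed by linear
interpolation onto the new grid, with output length
`round(n * target/rate)`. A frequency-domain anti-alias filter was
chosen over a high-order IIR because a Butterworth of sufficient order
at a normalized cutoff of ~0.045 (2 kHz from 44.1 kHz) is numerically
fragile in transfer-function form; the FFT operator is exactly
zero-phase and stable at any length. Upsampling is refused: annotations
and features are only defined at or below the original rate.
Segmentation boundaries, stored 0-based and half-open at the original
rate, are rescaled proportionally and rounded after resampling.

## The feature census

The 200-name census is fixed and canonical:

* a common block per interval (29 names x 4 intervals = 116): raw energy
  and zero-crossing count; energy/RMS in linear and dB scale for the
  wide 25–1000 Hz band and for five sub-bands 25–45, 45–80, 80–200,
  200–400, 400–1000 Hz; the sub-200 Hz spectral centroid `fc`; its
  octave deviation `oct` from the per-point mean centroid of the same
  interval label; and the relative interval length `trel`;
* a timing block for S1 and S2 only (22 x 2 = 44): absolute extrema
  values and normalized times, means/sds of local-extrema and
  zero-crossing times and their successive differences, extrema counts,
  derivative-discontinuity count, and the position skewness of the
  maximum absolute value;
* an envelope block for m1 and m2 only (19 x 2 = 38): quadratic envelope
  coefficients, quarter-wise energy/mean/sd profiles, whole-interval
  mean/sd, zeros per second, and position skewness;
* two per-point globals: beats per minute and the relative cycle length
  (2).

116 + 44 + 38 + 2 = 200. Filters are 4th-order Butterworth applied
forward–backward (zero phase); the 400–1000 Hz band at the 2 kHz rate is
realized as a high-pass at 400 Hz because 1000 Hz is the Nyquist
frequency. dB values are `10 log10(x + 1e-12)`, so silence reads
−120 dB. The spectral "central frequency" is implemented as the
magnitude-weighted DFT centroid over (0, 200] Hz (DC excluded, zero on
silent intervals); a peak-frequency reading was the alternative, but the
centroid is continuous in the data and degrades gracefully on noisy
intervals. The envelope is the magnitude of the analytic signal smoothed
by a 10 ms moving average before the least-squares quadratic fit on time
normalized to [0, 1]. Local extrema are samples strictly greater
(smaller) than both neighbours, plateaus counted once at their first
sample; event times are normalized by interval length; statistics
undefined for degenerate inputs (constants, too few events) return 0.
The derivative-discontinuity counter thresholds the second difference at
4 x its MAD (with a tiny absolute floor so exact lines do not count
their floating-point jitter), merging contiguous exceedances into one
event. Zero crossings require strictly opposite signs, with a run of
exact zeros separating opposite signs counted once. Quarter profiles
give remainder samples to the fourth quarter. Cycle features are
computed on the raw (unnormalized) amplitudes.

Per-point references (`oct`, `trel`, `bpm`) are computed over all cycles
of one auscultation point, which makes features of one cycle depend on
its point context — deliberately, as beats-per-minute and deviation
features are only meaningful relative to the patient's own rhythm and
spectrum.

## The synthetic cohort generator

Because clinical neonatal PCG data cannot be redistributed, the package
ships a generator whose defaults describe the study conditions used
throughout the tests: heart rate Normal(143, 7) bpm truncated to
[60, 250] (cycle ≈ 0.42 s, neonatal range), S1 70 ms at ~90 Hz, S2
50 ms at ~110 Hz as exponentially decaying sinusoid bursts with random
phase, additive white recording noise of sd 0.01 full-scale, systole
taking 40% of the non-transient cycle, five cycles per point, and five
points per patient. Murmurs are white noise shaped by the same
Butterworth band-pass operator the feature extractor uses (so generator
and analyser agree on what "in band" means), rescaled to sd
`murmur_gain x point_gain x noise_sd`, default band 200–400 Hz: CHD
patients receive it in m1 only, PDA patients in both m1 and m2
(continuous murmur), healthy patients none. Default point gains
(0.7, 1, 0.7, 0.7, 0.7) make the pulmonic point (2) loudest. All
randomness flows through one seeded generator per patient, derived
deterministically from the cohort master seed.

What the generator does **not** emulate: respiration and movement
artefacts, crying/speech interference, spectral colouring of real
stethoscope noise, inter-cycle morphology drift, split heart sounds, and
any hemodynamic murmur physics. Passing tests therefore demonstrate
that the pipeline recovers a band-limited amplitude cue under controlled
conditions and that its evaluation machinery is leak-free — not that it
reaches any particular accuracy on clinical recordings.

`inject_patient_offsets()` adds a per-patient constant to every feature
column (drawn at `offset_sd` x the column's cohort sd). It is a
controlled stand-in for patient-identity confounds and exists to make
the leakage comparison between split regimes expressible at desk scale.

## Boosting

The reference booster implements exact greedy regularized boosting for
binary logistic loss: base score at the log-odds of training prevalence,
per-round gradients `g = p − y` and Hessians `h = p(1 − p)`, candidate
thresholds at midpoints between consecutive sorted unique feature
values, split score `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ`
(split rejected when negative; ties broken by lower feature index, then
lower threshold), leaf weights `−G/(H+λ)` shrunk by `eta`, row/column
subsampling through the run's seeded generator, and per-feature gain
accumulation. With both sampling fractions at 1 the fit is fully
deterministic, and `keep_instances = TRUE` records each node's instance
set so every split and leaf can be audited against exhaustive
enumeration — the package's own tests do exactly that.

The production path delegates the same contract to xgboost (single
thread, seeded, base score set to the training prevalence) with AUC
early stopping: training halts after `patience` (default 50) rounds
without validation improvement, and predictions use the best round. The
agreement between the two implementations (probability RMS < 0.05 on a
seeded 200 x 20 task at eta 0.03, no subsampling) is asserted in the
test suite. Defaults when untuned: eta 0.03, max_depth 3, subsample
0.9, colsample_bytree 0.9, λ 1, γ 0, at most 1000 rounds.

## Evaluation design

AUC is the rank statistic (ties one half). Folds are stratified and
patient-independent: patients are shuffled within class and dealt
cyclically, with the deal position carried across classes so fold sizes
differ by at most one patient and per-fold class counts stay within one
of balance. Model selection uses 5x2-fold search over
(max_depth, subsample, colsample_bytree) scored by mean out-of-fold AUC
(default grid: depth {2,3,4,5} x fractions {0.5,0.7,0.9}²; the grid is
an optional argument of `run_setting()` since the search is expensive
relative to desk-scale cohorts), followed by a 10-fold CV ensemble of
early-stopped models whose members' held-out folds also provide the
reported validation mean ± sd. The test AUC is computed once over the
pooled out-of-fold per-patient probabilities.

The three split regimes mirror common evaluation mistakes: Setting 1 is
patient-independent in both loops; Setting 2 keeps the outer loop
patient-independent but shuffles the inner loop at cycle level; Setting
3 shuffles both. When a validation fold degenerates to one class (small
cohorts), that member trains to the round cap without early stopping and
contributes no validation AUC. Binary tasks exclude the third diagnosis
group entirely (PDA vs healthy drops CHD and vice versa); with three
labels, stratification acts on the two task classes.

Decision-level aggregation reduces cycle probabilities within each
point (mean, max, or pooling) and then across the patient (mean or
max); feature-level aggregation either averages all cycles into one
200-vector per patient or averages per point and concatenates into a
1000-vector. The baseline pools all cycle probabilities with the mean.

## Problem sizes and numerical choices

The shipped checks use: a 120-patient cohort (60 healthy / 40 PDA /
20 CHD, murmur gain 3, five cycles per point) for end-to-end recovery
and the Top-15 importance property; 20-patient cohorts (gain 1, three
cycles per point, offsets at 2 cohort-sds) across five seeds for the
leakage ordering; 50 x 8 datasets for split-by-split booster audits; and
200 seeded score sets for the AUC oracle. These sizes were chosen as
the smallest at which the properties are stable across seeds. Seeds
enter only through function arguments; repeated runs with the same seed
are identical to the byte in the written reports (timestamps are
deliberately excluded from artifacts).

## Known limitations

* The murmur model is an engineered stand-in; absolute AUC values on
  synthetic cohorts say nothing about clinical performance.
* Automatic segmentation, denoising, and recording-quality grading are
  out of scope; the pipeline trusts its annotations.
* The reference booster is O(rounds x nodes x features x n log n) in
  plain R — intended for audits and small fits, not production training.
* Confidence intervals for AUC are not provided.
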