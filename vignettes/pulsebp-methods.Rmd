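---
title: "Beat-to-beat cuff-less blood pressure estimation during arrhythmias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-to-beat cuff-less blood pressure estimation during arrhythmias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsebp)
```

## The estimation problem

During arrhythmias, blood pressure (BP) changes markedly from one heartbeat
to the next: a premature ventricular contraction (PVC) ejects against a
short filling time with reduced stroke volume, dropping systolic pressure by
tens of mmHg, and supraventricular runs sustain smaller but persistent
drops. Intermittent cuff readings cannot follow this, and intra-arterial
catheters are too invasive for routine monitoring. `pulsebp` implements an
indirect, cuff-less alternative: for each cardiac cycle it extracts timing,
slope, area and shape features from a synchronous ECG and finger
photoplethysmogram (PPG), and learns a per-patient regression from those
features to the invasively measured systolic (SBP) and diastolic (DBP)
pressures. After an initial calibration period against the invasive
reference, the model produces one SBP and one DBP estimate per beat from
ECG/PPG alone.

## Per-cycle features

Each beat is anchored at the ECG R-peak and described by five PPG
landmarks: the foot `F`, the maximal-upslope point `M` (peak of the first
derivative), the pulse peak `P`, the steepest-descent point `M'` and the end
foot `F'` (the next pulse's foot). The fifteen features are:

| Feature | Definition | Units |
|---|---|---|
| PTTrf, PTTrm, PTTrp | R-peak to `F` / `M` / `P` delay | s |
| AT | foot-to-peak time | s |
| AS | `(I(P) - I(F)) / AT` | intensity/s |
| FAS | `(I(M) - I(F)) / T_FM` | intensity/s |
| SYSAREA | area above `I(F)` between `F` and `P` | intensity · samples |
| DT | peak-to-end-foot time | s |
| DS | `(I(P) - I(F')) / DT` | intensity/s |
| FDS | `(I(M') - I(F')) / T_M'F'` | intensity/s |
| DIAAREA | area above `I(F')` between `P` and `F'` | intensity · samples |
| PIR | `I(P) / I(F)` on the raw signal | — |
| PW | `M`-to-`M'` time | s |
| HR | interval between successive PPG peaks | s |
| K | `(mean - min) / (max - min)` over `[F, F')` | — |

Pulse transit times are the physiological core: transit time shortens as
pressure rises, so the R-to-PPG delays carry direct pressure information.
The remaining features summarise the pulse contour, which reflects stroke
volume (ascending edge) and peripheral runoff (descending edge).

Interpretation choices where the feature definitions leave room:

* **`M'`** is the minimum of the PPG first derivative on the descending
  edge (steepest descent), not an amplitude-matched mirror of `M`; the
  mirror definition makes FDS and PW degenerate on asymmetric pulses.
* **FAS** interprets the "M-point intensity" as foot-referenced,
  `I(M) - I(F)`, so FAS is a slope commensurate with AS.
* **Areas** are reported in intensity·samples (no division by the sampling
  rate), with a trapezoidal end-correction (half of the edge's intensity
  difference subtracted from the inclusive sample sum). The correction
  removes the half-sample bias of the plain sum, so the discrete area
  converges to `fs` times the continuous area; on the analytic half-cosine
  fixture at 250 Hz it is exact to machine precision where the raw sum is
  2% high. Values are sampling-rate-dependent by construction, so models
  must be trained and applied at one rate.
* **PIR** is computed on the unfiltered PPG: its ratio depends on the DC
  baseline, which the detection filter distorts. All other shape features
  use a 10 Hz zero-phase low-passed copy.
* **HR** is kept as a peak-to-peak interval in seconds (not bpm). The
  first beat of a record has no preceding peak, so it contributes no row.
* **K** uses the standard characteristic-value form
  `(mean - min)/(max - min)` over the full cycle.

All sample indices are 1-based (R convention); a landmark at time `t`
satisfies `idx - 1 = round(t * fs)`.

## Detection chain

* **R-peaks**: zero-phase 5--20 Hz Butterworth band-pass, squared
  derivative, 150 ms moving-window integration, threshold at 20% of the
  99th envelope percentile, 250 ms refractory period. The squared
  derivative is polarity-blind, so widened/inverted PVC complexes are
  detected without special handling.
* **PPG fiducials**: the upstroke is found as the derivative maximum in a
  0.05--0.9 s window after each R-peak, gated at 2% of the record's maximal
  slope (windows with no real pulse are skipped and counted); the foot is
  the last non-positive-slope sample walked back from `M`, refined to the
  raw-signal minimum; the peak is the first non-positive-slope sample after
  `M`, refined to the raw maximum. `F'` is the next beat's foot, or the end
  of the decay for the final beat. Beats violating the ordering
  `r < F <= M <= P <= M' <= F'`, or with `F - r` outside [0.05, 0.5] s, are
  skipped.
* **Pressure cycles**: diastolic troughs of the 10 Hz low-passed arterial
  waveform (local minima, clusters within 250 ms collapsed to the deepest),
  refined to the raw minimum within ±80 ms; each beat owns the half-open
  trough-to-trough cycle starting within 0.6 s after its R-peak. Reference
  SBP/DBP are the cycle maximum/minimum.
* **Quality filter**: per-beat PPG energy `sum((x - mean)^2)` over
  `[F, F')`; a beat is excluded when its energy deviates from the record
  mean by more than 2 sample standard deviations (`ddof = 1`; the threshold
  is configurable). The rule is applied once over all beats, not iterated.
  Quality-failing beats are retained in the feature table with
  `quality_pass = FALSE`; model training uses only passing beats.

## Models and evaluation

For each patient the beats are split chronologically 6:2:2 into
train/validation/test. Chronological (rather than shuffled) splitting is
the default because beats are a time series: shuffling would place
near-duplicate neighbouring beats on both sides of the train/test boundary
and flatter the error estimates. A seeded random mode is available.

Four regressors are trained per patient and per target: a full-depth
regression tree (DTR), RBF-kernel support vector regression (SVR) with an
exhaustive validation-set grid search over `C` in {0.1, 1, 10, 100} and
`gamma` in {0.001, 0.01, 0.1, 1} (features standardised with training
statistics only), AdaBoost.R2 (50 depth-3 tree learners, linear loss,
weighted-median prediction) and a 50-tree random forest (RFR). The
algorithm with the lowest mean validation RMSE across patients is selected;
exact ties break by the fixed order DTR, SVR, AdaboostR, RFR. Paired
two-sided t-tests on per-patient RMSEs compare algorithms.

Feature importance uses the random forest's impurity importances
`omega_ij`, normalised per patient (`FI_ij = omega_ij / sum_j omega_ij`,
summing to 1) and averaged across patients. Normalising before averaging
keeps patients with large absolute impurity from dominating the group
ranking.

Evaluation reports RMSE, mean error (ME), sample SD of error (STD), MAE and
Pearson r; the identity `RMSE^2 = ME^2 + STD^2 (n-1)/n` holds for every
report and is asserted in the tests. The AAMI verdict requires
`|ME| <= 5`, `STD <= 8` mmHg and at least 35 subjects; BHS grades count
cumulative percentages of absolute error within 5/10/15 mmHg with inclusive
thresholds (A: 60/85/95, B: 50/75/90, C: 40/65/85, else D); Bland-Altman
limits are `ME ± 1.96 STD`. Group results pool all test-set beats across
patients (per-patient aggregation is available from the per-patient
metrics).

## The waveform simulator

Clinical recordings with synchronous ECG, PPG and intra-arterial pressure
during arrhythmias are not publicly deposited, so the package includes a
generative simulator that makes every stage testable against ground truth.
It emulates the statistical structure of arrhythmic hemodynamics, not
cardiovascular physics:

* **Rhythm**: sinus beats at `base_hr` with relative timing jitter
  (SD 3% by default); PVCs arrive at a coupling interval of 0.6 of the
  sinus interval with a compensatory pause (the pair spans two sinus
  intervals) and carry stroke amplitude ~0.45; supraventricular runs of
  3 + Geometric(0.4) beats at 0.6 of the sinus interval with stroke ~0.75.
* **Pressure rule**: `SBP_i = a0 + a1 RR_{i-1} + a2 stroke_i + noise` with
  defaults a0 = 60 mmHg, a1 = 25 mmHg/s, a2 = 35 mmHg and 2 mmHg noise SD.
  A 1 s sinus beat with unit stroke gives 120 mmHg; PVCs drop SBP by
  ~30 mmHg and run beats by ~17 mmHg, reproducing the magnitude ordering
  (ventricular >> supraventricular >> sinus) reported for clinical
  beat-to-beat BP changes. `DBP_i = 0.55 SBP_i + 10 + noise/2` keeps pulse
  pressures realistic and SBP > DBP.
* **Transit time**: `ptt_i = 0.35 s - 0.0015 s/mmHg * SBP_i` plus 3 ms
  noise, clipped to [0.05, 0.5] s — higher pressure, shorter transit.
* **Waveforms** at 250 Hz: a biphasic QRS template per beat (widened,
  inverted for PVCs); a positive-baseline (1.0 a.u.) PPG pulse whose foot
  falls exactly at `beat_time + ptt`, raised-cosine upstroke over 30% of
  the beat interval, raised-cosine decay with a small log-normal dicrotic
  lobe, amplitude proportional to stroke; an arterial pressure pulse per
  cycle spanning exactly `[DBP_i, SBP_i]`, with a one-sample end-diastolic
  nadir so each trough is a unique strict local minimum and per-cycle
  extrema recover the scheduled pressures exactly on noise-free records.
  Optional Gaussian noise is relative to each channel's pulse amplitude;
  an `artifact_fraction` of beats have their PPG pulse amplified 5-fold to
  emulate motion artifacts. The record is padded past the requested
  duration just enough to close the final cycle.
* **Determinism**: one seed drives all draws; identical configurations
  give bit-identical records. The caller's RNG state is untouched.

What the simulator does *not* model — and hence what passing tests do not
show about clinical data: Windkessel dynamics and reflected waves,
respiration coupling, baroreflex feedback, sensor drift, morphology change
under vasoconstriction, 12-lead ECG, atrial-fibrillation-specific
irregularity. The simulator's feature-to-pressure relation is, by
construction, learnable from the extracted features; clinical accuracy
claims require clinical data.

A feature-level generator (`simulate_feature_cohort()`) draws the
transit-time feature uniformly and sets
`SBP = 150 - 200 * PTTrm + N(0, 3 mmHg)` with independent nuisance
features; it benchmarks the regression and importance machinery against a
known rule: per-patient test RMSE should approach the 3 mmHg noise floor
and `PTTrm` should top the group importance ranking.

One known limitation of the global energy quality rule, visible in the
simulator: a 5-fold artifact on a low-stroke ectopic beat has energy
comparable to a clean sinus beat, so record-level 2-SD thresholding cannot
flag it. Under homogeneous sinus rhythm the filter removes essentially all
artifact beats while losing under 5% of clean ones; under heavy ectopy its
sensitivity drops. A per-morphology-class energy rule would be needed for
clinical use.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 3--10 simulated
patients with 100--240 s records (roughly 120--300 beats each) and
feature-level cohorts of 10 patients x 500 beats; these sizes give stable
statistics for every assertion while keeping a full run within a few
minutes on one core. Fiducial recovery is asserted within ±2 samples at
250 Hz; discrete areas within 2% of the continuous value; importance
normalisation within 1e-9. Zero-phase filtering uses mirrored edge padding
of one second to avoid start-up transients. Degenerate inputs (flat edges,
zero pulse amplitude, constant cycles, zero-variance targets) are flagged
or rejected with explicit errors rather than propagated as NaN.
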