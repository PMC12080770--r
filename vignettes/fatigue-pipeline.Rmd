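---
title: "Grading and predicting operational fatigue from HRV: methods and design"
author: "hrvFatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading and predicting operational fatigue from HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvFatigue)
```

This vignette explains the models behind the package, the parameters that
matter, the design decisions taken where the problem left them open, and
what the synthetic cohort does and does not demonstrate about real data.

## The measurement model

The pipeline targets the graded-treadmill protocol: each subject walks
stages of fixed duration (default 4 minutes) at speeds rising in 1 km/h
increments from 4 km/h; RR intervals (ms between successive ECG R-peaks)
are recorded continuously, and after each stage the subject reports a Borg
6–20 rating of perceived exertion and performs a simple reaction time test.
One subject-stage is one observation; the default 6 × 7 design gives 42.

### HRV features

From each stage's RR series we compute, in fixed canonical order
(`hrvFeatureNames()`): mean RR, HR = 60000/meanRR, SDNN, RMSSD, LF, HF,
LF/HF, SD1, SD2, SD2/SD1.

Conventions, chosen once and used everywhere:

* **SDNN** uses the sample (n−1) standard deviation, the usual reporting
  convention. Inside the Poincaré identities we use the population (1/n)
  variance instead, so that `sd1 = rmssd/√2` holds exactly for zero-mean
  successive differences and `2·sdnn_pop² = sd1² + sd2²` holds by
  construction (`sd2 = sqrt(2·var_pop − sd1²)`, floored at 0). Both
  conventions are documented on `poincare()`.
* **Spectral analysis** follows the short-term HRV standard: LF
  0.04–0.15 Hz, HF 0.15–0.40 Hz, computed on the tachogram resampled at
  4 Hz by cubic-spline interpolation and analysed with a Welch periodogram
  (Hann windows of at most half the record — 256 samples for a 4-minute
  stage — 50% overlap, per-segment mean removal). The estimator is
  calibrated so a sinusoid of amplitude A integrates to band power A²/2;
  powers are reported in absolute ms². The LF/HF ratio is invariant to that
  unit choice.
* **Degenerate ratios** (SD2/SD1 with SD1 = 0, LF/HF with HF = 0) are
  returned as `NA`, never infinity.
* **Artefact guard.** No ectopic-beat correction is attempted; inputs are
  assumed clean, and any interval outside 300–2000 ms is rejected with an
  error naming the guard. Stages are analysed whole (no sub-windowing),
  matching the 4-minute protocol unit.

### The composite fatigue index

Borg rating and reaction time are combined into a single index by the
entropy weight method. Each feature is min-max normalized
(`x' = (x − min)/(max − min)`), shifted by +0.001 so logarithms stay
finite, converted to per-sample proportions, and scored by information
entropy `e_j = −(1/ln n) Σ_i p_ij ln p_ij` (natural logarithm). The weight
of feature j is `w_j = (1 − e_j)/Σ_k (1 − e_k)`: a more dispersed feature
is more informative and weighs more. The index is
`F = w_R·R + w_B·B ∈ [0, 1]`, with both components treated as positive
indicators (larger = more fatigued). The reference study's own data gave
`F = 0.39R + 0.61B`; those weights ship as `referenceWeights()` because the
underlying raw data are not deposited, while `computeWeights()` derives
cohort-specific weights from data.

Two normalization corner cases are fixed by fiat, as the only internally
consistent choices: a constant feature normalizes to all zeros (hence
uniform proportions, entropy 1, weight 0), and F is clipped to [0, 1] only
when floating error exceeds a bound by less than 1e-9 — larger violations
are errors, not silent repairs. The staged `FeatureMatrix` class
(raw → normalized → shifted) exists purely to make out-of-order application
of these steps a type error rather than a silent numerical bug.

### Grading by clustering

K-means (Lloyd's algorithm, Euclidean distance) runs on the normalized
(R, B) plane with 10 seeded restarts, initial centroids sampled uniformly
without replacement from the data points, assignment ties broken toward the
lowest centroid index, and at most 100 iterations. An emptied cluster is
repaired by relocating its centroid to the point farthest from its assigned
centroid and reassigning; because no point had chosen the empty centroid,
this cannot raise the within-SS, so the per-iteration trace is provably
non-increasing (and is asserted at run time). The number of clusters is
scanned over K = 2…10 by mean silhouette width
`s_i = (b_i − a_i)/max(a_i, b_i)` (singleton-cluster members score 0),
using the best restart per K — on the question of whether to average over
restarts instead, we use the best restart because it is the model actually
retained downstream, and record the choice here.

On well-separated data the silhouette peaks at K = 2, which distinguishes
only "fresh" from "fatigued"; for an operationally useful grading the
pipeline clusters at a configurable K (default 5, matching the five-level
reference table), extracts per-cluster per-feature [min, max] thresholds
ordered by the weighted centroid, combines them into F bands
(`F_lo = Σ w_j lo_j`, `F_hi = Σ w_j hi_j`), and consolidates overlapping
bands.

**Consolidation rule.** Adjacent bands merge when one contains the other or
when their intersection is at least 20% of the narrower band's width,
greedily in ascending order, the merged band spanning the union. The 20%
default was set by analysing the reference five-band table: its printed
band overlaps are 20% (levels 1–2), 20% (2–3, diluted below threshold once
1–2 merge), 0% (3–4) and 40% (4–5), so a 20% threshold with greedy
ascending merges is the weakest rule that reproduces the published
consolidation {1,2}→mild, {3}→moderate, {4,5}→severe — a 50% rule, for
comparison, merges nothing there. On synthetic cohorts the outcome is
data-driven: well-separated clusters legitimately survive unmerged, and the
pipeline reports however many consolidated bands the data support. The
canonical 3-level bands (mild [0, 0.27), moderate [0.27, 0.66), severe
[0.66, 1], boundaries belonging to the upper level) are available as
`referenceFatigueBands()`.

### The prediction network

A 10-8-1 feedforward network maps the ten HRV features to F: tanh hidden
units, linear output, inputs and target scaled to [−1, 1] by min-max fit on
the training split only (`scaleFit()`/`scaleApply()`, inverted on
predictions). Defaults follow the reference training regime: learning rate
0.01, at most 1000 epochs, early stop at training MSE 1e-5 (measured on the
scaled target, the MATLAB `newff` convention), weights initialized
uniformly on (−0.5, 0.5) from a seeded stream.

The optimizer is full-batch gradient descent with an adaptive step: a step
that would raise the loss is halved and retried; a successful step is
probed at twice the size while that keeps improving; and the working rate
carries over to the next epoch. Every accepted step strictly lowers the
loss, so the training history is monotone non-increasing by construction.
A fixed-rate variant was tried first and rejected: on this problem's
ill-conditioned, strongly collinear features it stalls an order of
magnitude short of the achievable fit within the 1000-epoch budget, whereas
the adaptive step reaches it while remaining plain gradient descent (the
same family as MATLAB's `traingda`). Divergence (MSE > 1e6) aborts with an
error suggesting a smaller rate. Gradients are analytic backpropagation,
tested against central finite differences to 1e-6.

Evaluation reports MAE, MSE, RMSE and R² on a seeded 19:2 hold-out split
(38 train / 4 test on 42 samples — chosen over the alternative 9:1 ratio
because it is integral at this n) and by 5-fold cross-validation. Because
an R² estimated on 4 points is extremely noisy, the package's headline
held-out metric is the *pooled* cross-validated R²: all 42 predictions,
each from a model that never saw that sample, scored together. A
"correct classification rate" for a continuous regression output is not a
well-defined metric and is deliberately not implemented; R² and the error
metrics are the reported surface.

## The synthetic cohort: what it emulates

The generator exists so the pipeline is testable end to end with known
ground truth. Per subject it draws a physiological profile — resting HR
uniform on 60–70 bpm (inside the 50–90 inclusion window), maximal HR
188–192 bpm, an HR response of 10–13% of heart-rate reserve per km/h,
baseline SDNN 55–75 ms, baseline reaction time 285–315 ms — and defines
latent fatigue as the heart-rate-reserve fraction in use,
`tf = (HR − rest)/(max − rest)`, clipped to [0, 1]: simple, monotone in
stage, and physiologically interpretable. Observations follow:

* Borg = round(6 + 14·tf + ε), clipped to [6, 20] — rising toward 20 at
  exhaustion;
* reaction time = baseline·(1 + 0.5·tf) + ε — a 50% slowdown at full
  fatigue, in line with reported fatigue-related SRT lengthening;
* SDNN target = baseline·(1 − 0.85·tf), floored at 5 ms; LF/HF target
  = 1 + 4·tf (sympathetic predominance with load).

RR series are built as a base interval 60000/HR plus two sinusoids at 0.10
and 0.25 Hz — the centres of the LF and HF bands, so band powers are
analytically attributable — plus white jitter. Sinusoid amplitudes are set
from the LF/HF target with an analytic correction for the broadband jitter
power falling in each band, and the jitter is rescaled so the realized
series SD equals the SDNN target exactly. The modulation is evaluated on
the nominal beat grid and centred, so the series mean is exact too.
Intervals are finally clamped to a 310–1990 ms plausibility window (the
feature guard is 300–2000 ms). Noise channels (defaults: Borg 0.6 RPE
units, reaction time 10 ms, HR 2 bpm, SDNN 3 ms) were calibrated once,
analytically, so that the part of the index variance unpredictable from the
HRV features is around 7% — the regime in which the reference study's
network operated (R² ≈ 0.93) — and are not tuned thereafter.

Reproducibility: one seeded stream per cohort draws profiles first, then
observation noise in fixed order; per-series jitter seeds are derived
deterministically from (cohort seed, subject, stage), so subject 3/stage 2
is bit-identical whether the protocol has 5 or 9 stages. Identical seeds
give byte-identical on-disk cohorts.

**What passing tests do not show.** The generator's fatigue dynamics are
deliberately simple: fatigue is memoryless in stage (no accumulation or
recovery), RR spectra are two tones plus white noise (real tachograms have
1/f backgrounds, respiratory sinus arrhythmia coupled to breathing rate,
and ectopy), Borg noise is homoscedastic, and no heat, load-carrying or
smoke stressors exist. Recovery of the index from features on this cohort
demonstrates that the pipeline's plumbing, scaling and optimizer are
correct — not that ten HRV features suffice to predict fatigue in the
field. The one resting-baseline recording the protocol takes before stage 1
is not an observation (the default cohort excludes it, which is why
6 × 7 = 42).

## Numerical choices and degenerate inputs

* Feature extraction requires ≥ 30 beats; spectral analysis ≥ 120 s.
* `selectK` requires max(K) ≤ n; `kmeansFit` errors for K > n; K = n is
  the exact zero-within-SS solution.
* Weight derivation errors when every feature is constant ("no
  discriminating feature") rather than returning NaNs.
* `classifyLevel` errors outside [0, 1] (with the same 1e-9 float
  indulgence as the index itself); bands are half-open with boundaries
  belonging to the upper level, and the top band closed at 1.
* Cross-validation derives per-fold initialization seeds from the config
  seed, so fold models are independent but reproducible.
* All JSON artifacts embed the seed; `report.json` embeds the full
  configuration, and a rerun with the same configuration is byte-identical.

## Problem sizes used by the test suite

The suite runs the full default study design throughout: 42-observation
cohorts, 4-minute stages, the complete K = 2…10 silhouette scan, 1000-epoch
training, and a ten-seed replication of the cross-validated recovery check.
These are the study's own scales; nothing is miniaturized.

## Known limitations

* The published five-level threshold table is reproduced structurally
  (min/max extraction, weighting, consolidation), but its exact numbers are
  not recomputable without the original cohort; they ship as reference
  constants. For the published composite-index bands, only the moderate
  band (0.27, 0.66) is exactly the weighted recombination of the feature
  bounds; the other four differ slightly in print and are kept verbatim.
* The published feature order for clustering ("Borg first") conflicts with
  the weighted band arithmetic, which is only consistent if the 0.39 weight
  multiplies reaction time. The package sidesteps the ambiguity by keying
  weights to named features everywhere; positional weights are an error.
* A Levenberg–Marquardt trainer (named as an alternative in the reference
  description of the regime) is not provided; the gradient-descent path is
  the one whose reported metrics the package mirrors, and the adaptive step
  covers the convergence gap.
* No real-device ingestion: `.rr` text files and CSV only.
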