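---
title: "Models and methods behind pupilperim"
author: "pupilperim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupilperim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pupilperim` implements the analysis chain of a chromatic-pupilloperimetry
case-control study — per-target pupillary light reflex (PLR) kinetics,
per-parameter boosted classification, bootstrap out-of-bag AUC-ROC
inference, and focal latency comparison — together with a synthetic-cohort
generator that provides ground truth for every stage. This vignette is the
package's account of the underlying models, the operational definitions,
and the numerical and design choices, so that a user can judge what a
passing validation suite does and does not demonstrate.

## 1. The generative waveform model

A single trace is a pupil-diameter time series sampled from stimulus onset
(`t = 0`) on a uniform grid. The noise-free transient model is

$$D(t) = D_b - A\,s(u)\,r(u) - g(u), \qquad u = t - L,$$

with baseline diameter $D_b$ (mm), response latency $L$ (s), contraction
amplitude $A$ (mm), and

* a gamma-shaped contraction kernel
  $s(u) = (u/t_p)^2 \exp\!\big(2(1 - u/t_p)\big)$ for $u \ge 0$ (0
  otherwise), chosen for its smooth onset (zero velocity and finite
  acceleration step at $u = 0$), its closed-form peak ($s = 1$ exactly at
  $u = t_p$), and analytically tractable extrema — the maximal contraction
  velocity sits at $u = t_p(1 - \sqrt{2}/2)$, which the test suite uses as
  an oracle;
* an exponential redilation factor
  $r(u) = \exp\!\big(-\max(0, u - t_p)/\tau_r\big)$, equal to 1 up to the
  trough so the waveform is continuous (but kinked) at its minimum;
* for bright stimuli only, a sustained (melanopsin-like) component
  $g(u) = A_s(1 - e^{-u/\tau_s})$ during the stimulus, decaying with time
  constant $3\tau_s$ after light offset;
* i.i.d. Gaussian measurement noise per sample.

Protocol constants follow the chromatic pupilloperimetry design the
package models: dim red (624 nm, 1000 cd/m²) and dim blue (485 nm,
170 cd/m²) stimuli of 1 s with 4 s of recording at all 54 targets of the
24-2 visual-field pattern; bright red/blue stimuli (6000 cd/m²) of 8 s
with 16 s of recording at 4 targets; background 0.04 cd/m². The 24-2 grid
is built from rows $y \in \{\pm 3, \pm 9, \pm 15, \pm 21\}$ degrees with
$|x| \le 21$ plus two nasal-extension points at $|x| = 27$ on the
$y = \pm 3$ rows (54 locations); the left-eye grid is the horizontal
mirror with identical indices.

### Cohort-level structure

`cohortConfig()` defaults encode the reference case-control design: 186
subjects (125 FH+, 61 FH−), ages drawn per group from truncated normals
(FH+ 59.9 ± 6.7, FH− 59.1 ± 5.6, range 44–71 years), and a focal latency
effect at the two peripheral temporal-field targets of the right eye
(indices 27 and 36, at (21°, ±3°)) under dim blue light: FH+ subjects
respond at 0.450 s there versus 0.477 s for FH− and for all other targets.

Latency is decomposed as *shared subject trait* + *per-target jitter* +
*group shift at effect targets*:

| parameter | default | rationale |
|---|---|---|
| `latencyFHneg` | 0.477 s | reference latency, shared by all non-effect targets |
| `latencyFHpos` | 0.450 s | a ~27 ms focal shortening, the effect under study |
| `betweenSubjectSd` | 0.020 s | ~4% CV, a realistic between-subject spread for PLR latency |
| `targetJitterSd` | 0.010 s | independent per-target variability |
| `noiseSd` | 0.010 mm | diameter noise of a modern IR video pupillometer at 30 Hz |
| `samplingRate` | 30 Hz | configurable; video-camera class hardware |
| `missingnessRate` | 0.0076 | fraction of responses unusable at the feature level |
| `blinkRate` | 0.05 | traces receiving a blink gap |

The dispersion defaults were fixed once, from what we consider plausible
instrument and population characteristics, before any classifier was run
on them; they are deliberately chosen so that the injected ~30 ms effect
is detectable but not trivial (the optimal single-feature separation is
far from perfect). Waveform shape parameters are drawn per trace:
$A \sim 0.90 \pm 0.08$ mm (dim; bright 1.6 ± 0.12), $t_p \sim 0.80 \pm
0.04$ s (bright 1.1), $\tau_r \sim 1.2 \pm 0.1$ s (bright 3.0), $D_b$ per
subject $5.5 \pm 0.4$ mm, all truncated to physiological ranges; bright
blue adds $A_s = 0.50 \pm 0.05$ mm of sustained response (bright red only
0.15, mirroring the much weaker melanopsin drive at long wavelengths).

Blink artifacts are contiguous sample gaps of 0.1–0.25 s; a trace whose
gap begins inside the first 2.5 s is regenerated, emulating the automatic
retest rule of the acquisition protocol, and the retest count is recorded.
Missingness is applied at the *(subject, eye, condition, target)* response
level — all 17 parameters of a masked response become missing feature
cells — because in the modelled workflow imputation operates on feature
cells, not raw samples.

### What the simulator does not emulate

Real recordings have autocorrelated (not white) noise, gaze- and
accommodation-driven drifts, consensual-reflex coupling between eyes,
target-eccentricity-dependent amplitudes, and non-Gaussian
between-subject structure. Group differences in real data need not be
confined to latency, nor to two targets. Passing validation on this
simulator therefore demonstrates that the *pipeline* is correct and
calibrated (it finds an effect exactly where one was injected and reports
chance-level discrimination when none was), not that any particular
clinical effect size is recoverable from real recordings.

## 2. The 17 kinetic parameters

`extractFeatures()` computes, per trace: contraction amplitude AC (mm),
percentage of pupil contraction PPC (%), pupil response latency PRL (s),
latency of maximal pupil contraction LMP (s), maximal contraction
velocity / acceleration / deceleration (MCV mm/s, MCA mm/s², MCD mm/s²)
with latencies LMCV, LMCA, LMCD, the redilation counterparts MRV, MRA,
MRD, LMRV, LMRA, LMRD, and percent pupil recovery PRP (%). All latencies
are measured from stimulus onset.

Operational definitions (these are the package's explicit stand-ins; they
are isolated behind `plrSettings()` so an alternative reading can be
swapped in without touching callers):

* **Smoothing.** Savitzky–Golay local polynomial fit, order 2, 7-sample
  window at 30 Hz (both configurable); velocity and acceleration are the
  analytic derivatives of the local fit. Missing samples are linearly
  interpolated first and re-flagged; traces with more than 50% missing
  samples are rejected (all features undefined).
* **Onset (PRL).** The trigger is the first time velocity stays below
  $-\theta$ for three consecutive samples, with the adaptive threshold
  $\theta = \max(0.1\,\mathrm{MCV},\ 3\,\hat\sigma_v)$, where
  $\hat\sigma_v$ is the robust (MAD) SD of pre-onset velocity. PRL is the
  linearly interpolated crossing of $\theta$, minus a correction for the
  noise-driven part of the threshold obtained by extrapolating along the
  secant to a higher crossing. Two numerical choices matter here. First,
  onset detection uses a dedicated 5-sample derivative window: a wider
  window leaks the post-onset decline into pre-onset samples and biases
  any crossing estimate early by 1–3 samples. Second, we interpolate to
  the *threshold* crossing rather than to the zero-velocity crossing: the
  smoothed velocity of a hinge-shaped onset goes negative ~2–3 samples
  before the true onset, so a zero-crossing rule is biased early by that
  amount, while the threshold crossing of the rising limb (which is
  locally linear) lands within a fraction of a sample. On noise-free model
  traces the residual bias is about −0.35 samples (worst case 0.7); at
  0.02 mm noise the median absolute error stays below one sample. If MCV
  does not exceed the noise floor, PRL — and every downstream parameter —
  is undefined (`NA`), which propagates as a missing feature cell;
  undefined is a value, not an error.
* **Trough (LMP, AC).** The redilation factor makes the waveform minimum a
  kink (zero left-derivative, positive right-derivative), and the argmin
  of any symmetrically smoothed trace is biased 1–2 samples early. The
  trough is therefore located on the *raw* trace within the smoothing
  half-width of the coarse smoothed argmin, and its value refined by an
  exact cubic through four samples around the argmin — shifted one sample
  left when the argmin sits just past the kink (detected by its excess
  over a parabolic extrapolation of the three preceding samples). This
  recovers the noise-free trough value to well under $10^{-3}$ mm and its
  location to ~0.1 sample.
* **Baseline** $D_b$ is the mean smoothed diameter over the samples more
  than two sample intervals before the detected onset (the protocol
  starts recording at stimulus onset, so there is no separate
  pre-stimulus window); with fewer than two such samples the first two
  samples are used. AC $= D_b -$ trough, PPC $= 100\,\mathrm{AC}/D_b$.
* **Windows.** Contraction window = [PRL, PRL + stimulus duration + 1 s]
  (trough search) and [PRL, LMP] (velocity/acceleration extrema);
  redilation window = (LMP, end of recording]. A contraction extremum of
  the wrong sign (e.g. no deceleration phase) is undefined. PRP
  $= 100\,(D_{end} - \mathrm{trough})/\mathrm{AC}$, clipped to [0, 100].

## 3. Feature tables and preprocessing

One table per (parameter, condition, eye): subjects × 54 features for dim
conditions, × 4 for bright — 17 × 4 × 2 = 136 tables for the full
protocol. Tables are `SummarizedExperiment`s (targets as rows, subjects as
columns, labels and ages in `colData`). Subjects lacking either eye are
excluded, mirroring the both-eyes-eligible inclusion rule.

Missing cells are mean-imputed and all features min–max scaled to [0, 1].
Both steps are *fitted on the in-bag subjects of each bootstrap replicate*
by default and applied to the out-of-bag subjects (test values clipped to
[0, 1]); this is the leakage-safe reading. A `preprocess = "global"`
switch reproduces the alternative whole-dataset reading. A constant
training column maps to 0.5 (any constant is equally uninformative), and
an all-missing in-bag column is filled with 0.5 rather than dropped so
that column alignment with the trained model survives resampling; the
standalone `imputeMean()` API instead drops such columns with a warning.

## 4. Classification and feature weights

`trainAdaBoost()` is discrete AdaBoost with depth-1 threshold stumps:
per round the (feature, threshold, polarity) triple minimising the
weighted 0–1 error, thresholds at midpoints between consecutive distinct
sorted values, stage weight $\alpha_t = \tfrac12\log((1-\epsilon_t)/
\epsilon_t)$, early stop at error 0 (after keeping the stump) or ≥ 0.5
(before). Training is fully deterministic — ties break to the lowest
feature index, then lowest threshold — so bootstrap reproducibility rests
on the resampling seeds alone. The default of 50 rounds is a conventional
small-ensemble choice; no hyperparameter tuning is performed anywhere in
the pipeline. The score is the signed margin $\sum_t \alpha_t h_t(x)$, and
AUC-ROC is computed in the Mann–Whitney rank form with ties counted ½.
A per-target **feature weight** is the normalised sum of $|\alpha_t|$ over
the stumps using that target — a definition, chosen as the natural
"relative weight" a stump ensemble assigns to a feature. A pure-R
exhaustive-search AdaBoost in the test helpers serves as the independent
oracle for the compiled implementation, and pROC cross-checks the AUC.

## 5. Bootstrap out-of-bag inference

Per replicate: draw, within each class, class-size samples with
replacement; subjects never drawn form the out-of-bag set; fit
preprocessing on the bag, train, score the out-of-bag subjects, record
AUC and the model's weight map. Replicates whose out-of-bag set lacks a
class are skipped and counted (not resampled). The reference protocol
uses B = 2000 replicates; summaries are the replicate mean ± SD, the
percentile 2.5/97.5% interval (the CI estimator is our choice among
non-parametric options), and the weight map averaged over replicates and
renormalised. Replicate seeds are drawn up front from the master seed
(`sample.int(2^31 − 1, B)`), so results are reproducible and independent
of evaluation order. For n = 186 the expected number of distinct
out-of-bag subjects is $n(1 - 1/n)^n \approx 68$, which is what the
package reports as `meanOobSize`.

Note that out-of-bag evaluation of an aggressively overfitting learner is
slightly conservative on null data, and the mean out-of-bag AUC of a
*single* finite cohort carries dataset-level luck of roughly ±0.03 at
n = 186 with 54 features; the calibration checks in the test suite
therefore average over several independent null cohorts.

## 6. Focal analysis

From the bootstrap-averaged weight map of a latency model,
`selectDiscriminativeTargets()` takes the targets whose weight strictly
exceeds a threshold (0.47 is the reference value used in the modelled
analysis; an empty selection is allowed and handled). Because the
absolute weight scale depends on the ensemble size and on how many
informative targets share the weight, the function also offers a
rank-based rule (`top = n`), which the validation suite uses with
`top = 2`. Each subject's focal value is the mean of the (raw,
pre-scaling) parameter over the selected targets; the aggregation rule is
a package choice. Groups are compared twice: a two-sided pooled-variance
t-test (Welch available by flag) and a general linear model
`value ~ group + age` whose adjusted group means are evaluated at the
overall mean age. Both p-values are Bonferroni-corrected by the number of
selected targets, `p → min(1, p·m)`.

## 7. Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
closed-form waveform quantities (trough value/location, maximal-velocity
latency) for the extractor; exhaustive enumeration for stumps and AUC;
hand-computed t statistics; and calibration/recovery properties of the
full chain on synthetic cohorts. The cohort sizes used there — the full
186-subject design for latency recovery, missingness accounting, null
calibration and signal recovery; 80-subject cohorts for the 50-run CI
coverage check; B = 100–200 bootstrap replicates — are the package's
choice of the smallest sizes at which the checked quantities are stable,
so the suite runs comfortably on one CPU.

## 8. Known limitations

* The 17 parameter definitions are explicit operational stand-ins; other
  instruments define AC/PRP (and latency reference points) differently.
  The `plrSettings()` indirection exists precisely so alternative
  definitions can be swapped in.
* The onset detector assumes a single contraction event after stimulus
  onset; oscillatory or multi-phasic responses (hippus) will confuse it.
* Min–max scaling and mean imputation are the modelled protocol's
  choices, not recommendations; both are sensitive to outliers.
* AdaBoost feature weights measure how often/strongly a target is used by
  stumps, which is not a causal or unique attribution when targets are
  correlated.
* The bright-light (sustained) branch shares the 17-parameter extractor;
  no melanopsin-specific metrics (e.g. post-illumination response at a
  fixed delay) are computed.
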