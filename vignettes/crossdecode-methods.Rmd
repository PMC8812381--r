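---
title: "Cross-task MVPA decoding on simulated blocked-design BOLD data"
author: "crossdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-task MVPA decoding on simulated blocked-design BOLD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdecode)
```

## The analysis this package implements

Multivariate pattern analysis (MVPA) decodes cognitive conditions from
distributed voxel activity rather than from single-voxel statistics. Its
cross-classification variant (MVPA-CC) asks a sharper question: does a
classifier trained to separate two conditions in one task carry information
into a *different* task? `crossdecode` implements the complete pipeline for a
two-task design in which subjects first watch penalty-kick videos under two
instructions — attending to movement kinematics (ATT) versus kinesthetic
motor imagery of the kick (IMG) — and then perform a 4-alternative
penalty-reading task (predicting kick direction; chance 25%). The scientific
statistic is the *IMG proportion*: among penalty trials whose direction the
subject anticipated correctly, the fraction that the ATT-vs-IMG classifier
labels IMG. If imagery circuitry contributes to successful penalty reading,
this proportion exceeds the 50% two-class chance level.

Because no public data accompany this design, the package pairs the analysis
with a forward simulator whose ground truth makes every stage testable: the
full chain is simulate → single-trial GLM → decode → cross-classify →
group inference, plus a packaged experiment that demonstrates a well-known
pitfall of within-task cross-validation in blocked designs.

## The forward model

`simulateSubject()` draws, per subject:

* **Event schedules.** Training: 4 runs × 4 mini-blocks × 3 video trials
  (clip duration uniform on 1.2–1.5 s). Inter-trial intervals are jittered
  on a 0.1-s grid between 2 and 8 s (mean 5 s), mini-block breaks between
  3 and 8 s (mean 5.5 s); each run opens with a 5-s instruction cue. In the
  blocked design each run carries one instruction, AABB or BBAA across the
  four runs. Transfer: a single 60-trial penalty-reading run with the same
  jitter structure. Trial counts are configurable; the defaults
  (48 training trials, 24 per class) keep the blocked structure that drives
  the confound while staying desk-scale, since the source design's block
  arithmetic does not pin down a unique per-run trial count.
* **Condition prototypes.** Two unit-norm, mean-zero voxel patterns with an
  exactly specified correlation (`patternOverlap`, default 0.3). Prototypes
  are spatially white — real activation maps are spatially smooth, which is
  one reason passing tests here do not certify behaviour on real data (see
  *Limitations*).
* **BOLD signal.** Each trial contributes
  `signalAmplitude × prototype × (boxcar ∗ HRF)` at TR = 2 s, on top of a
  low-frequency cosine drift (periods above 100 s, independent voxel
  loadings scaled by `driftAmplitude`) and stationary AR(1) Gaussian noise
  (`noiseSd`, `ar1Coef`). Training trials use their condition's prototype;
  transfer trials use the prototype of a *latent strategy* drawn per trial.
* **Latent transfer truth.** Outcome ~ Bernoulli(`pCorrect`); strategy IMG
  with probability `pImgGivenCorrect` on correct trials and
  `pImgGivenIncorrect` otherwise. The group IMG proportion estimates
  `pImgGivenCorrect`; its default, 0.622, matches the effect size the
  analysis is designed to detect.
* **Nuisance series.** Six smooth random walks standing in for motion
  parameters (only their role as regressors matters) and the global signal.

Default free parameters were fixed once at field-plausible values:
`noiseSd = 1`, `ar1Coef = 0.3` (a typical BOLD residual lag-1 correlation at
TR 2 s), `driftAmplitude = 1`, `signalAmplitude = 1`, `pCorrect = 0.5`.
Determinism: one root seed; per-subject streams are derived stably, so
adding subjects never perturbs existing ones, and identical configurations
give byte-identical TSV/JSON output.

## First-level model

`processRun()` mirrors the standard FSL-style first level:

1. **High-pass, 100-s cutoff** — implemented as a discrete-cosine basis
   projection rather than FSL's Gaussian-weighted running line; the two are
   spectrally equivalent for this purpose and the projection is
   deterministic and exactly idempotent. The same projection is applied to
   the trial and motion regressors so filtering cannot bias the estimates.
2. **5-mm FWHM Gaussian smoothing** on the 3-mm voxel grid, separable with
   boundary renormalisation (constants are preserved exactly).
3. **Least-squares-all single-trial GLM**: one double-gamma-convolved
   regressor per trial (all trials in one model), six motion columns, the
   global signal (recomputed as the mask mean of the *filtered* series,
   since the original mask definition is unstated), and an intercept.
   Ordinary least squares per voxel; per-trial t = β/SE at residual degrees
   of freedom; z via the t cumulative probability mapped through the
   standard-normal quantile, clamped at ±8.2 so saturated values stay
   finite for the classifier.

The double-gamma HRF uses the canonical constants (peak 6 s, undershoot
16 s, unit dispersions, undershoot ratio 1/6). Each component is a gamma
density parameterised with shape = delay/dispersion + 1 so its **mode sits
exactly at the stated delay**; the kernel is normalised to unit peak.
No prewhitening is applied (plain OLS); the consequence of serially
correlated residuals is not swept under the rug but quantified explicitly
by the confound experiment below. Slice-timing, motion correction and
registration are out of scope — inputs are already on a common grid.

## Decoding and inference

* `trainLinearSvm()`: soft-margin linear SVM (libsvm via e1071), cost 1, no
  feature scaling, deterministic for fixed input order. The hyperplane is
  stored explicitly; ties at the decision boundary go to the first stored
  label, deterministically.
* `crossValidate()`: stratified 10-fold cross-validation. Stratification
  preserves the class balance in every fold; fold assignment is otherwise
  run-agnostic, deliberately retaining the within-task leakage that the
  confound experiment studies.
* `permutationTestAccuracy()`: 1,000 label shuffles, each rerunning the full
  cross-validation; add-one p-value `(1 + #{null ≥ observed})/(1 + nPerm)`
  so p is never zero.
* `groupWeightTtest()` + `thresholdClusters()`: per-voxel one-sample t of
  fold-averaged weights against zero (a "test against a constant" is
  one-sample by definition), thresholded at t > 1.7 and retaining connected
  components larger than 200 voxels (26-neighbour connectivity by default,
  6 available).
* Cross-classification: a single refit on all training trials (not an
  ensemble of fold models) is applied to every transfer trial;
  `imgProportion()` is computed over correctly anticipated trials only, and
  subjects with no correct trials are excluded with an error. Per-subject
  permutation nulls shuffle the training labels and refit; the subject-level
  p is one-sided (greater than chance, matching the directional
  hypothesis), the group-level t-test against 0.5 two-sided.

## The blocked-design confound experiment

When all trials of a condition share an acquisition run, slow noise (drift,
AR(1)) is shared within condition. Single-trial estimates from the same run
are then correlated, cross-validation folds that mix runs violate the
train/test independence assumption, and within-task accuracy is inflated
even with *zero* condition signal. Cross-classification is immune: the
transfer task is an independent acquisition, so its trials share no noise
with the training runs.

`runInflationExperiment()` packages this as a simulation: 50 null subjects
(signal amplitude 0) per arm. The *blocked* arm uses run-blocked
instructions with AR(1) coefficient 0.6 and strong drift; the *interleaved*
arm randomises labels within runs **and uses white, drift-free noise**. The
control must be the exchangeable null: interleaving labels alone does not
restore calibration — with shared slow noise and interleaved labels,
cross-validated accuracy is in fact biased *below* chance, because the
dependence leaks anti-information about held-out trials. The experiment
reports, per arm, the mean null cross-validated accuracy and the mean null
cross-classification proportion with Monte-Carlo standard errors. It
establishes the direction of the inflation, not its magnitude in any real
dataset. Reduced dimensions (125–200 voxels, 24 transfer trials) keep a
replicate cheap; the mathematics is unchanged.

## Numerical and design choices

* **Tolerances.** Prototype correlation is exact by construction (±1e−6
  asserted); jitter values are rounded onto the 0.1-s grid so serialisation
  round-trips exactly; z clamped at ±8.2; float32 NIfTI storage bounds
  volume round-trip error at ~1e−6 relative.
* **Degenerate inputs.** Single-class labels, rank-deficient designs (the
  collinear columns are named), events extending beyond a run (the trial id
  is named), zero correct transfer trials, and zero across-subject variance
  (infinite t sentinel plus flag) all raise or flag explicitly.
* **Grid geometry.** The voxel count is factorised into a near-cubic
  single-slab grid with 3-mm isotropic voxels and a whole-grid mask;
  anatomical realism is out of scope.
* **aCompCor.** The emulated first-level model contains motion and global
  signal regressors only; physiological-noise components are intentionally
  absent, matching the stated model.
* **Interfaces.** The pipeline is driven from R (`runPipeline()`,
  `pipelineConfig()`, YAML round-trip) rather than a shell executable; the
  exported functions are the command surface, and every stage writes
  BIDS-style TSV/NIfTI/JSON with a hash manifest for reproducibility.

## Problem sizes used in the tests

The shipped tests run the full chain at desk scale, chosen once as
realistic-but-small study conditions: 125–200 voxels, 4 training runs
(48 trials), 60 transfer trials (24 in the confound arms), 50 replicates for
calibration checks, 100–1,000 permutation iterations depending on the
check. Parameter-recovery checks use a high-SNR setting (signal amplitude
8–12, smoothing off — the generator's spatially white prototypes make
unsmoothed estimates the right recovery target), under which the group IMG
proportion recovers the generating `pImgGivenCorrect` within 0.05 across
{0.5, 0.7, 0.9}.

## Limitations

* The simulator omits spatial structure in activation patterns, head
  motion, physiological noise, multi-echo acquisition and surface
  geometry; calibration results here demonstrate the statistical machinery,
  not performance on real acquisitions.
* OLS without prewhitening means single-subject z-maps are not valid for
  inference on their own under autocorrelated noise; they are used only as
  classifier features, and the confound experiment quantifies the
  downstream effect.
* The inflation experiment establishes direction, not the share of any
  empirically observed accuracy attributable to leakage — that would
  require the original data.
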