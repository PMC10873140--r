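---
title: "Multivariate lesion-symptom mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate lesion-symptom mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a left-hemisphere stroke, most people with aphasia recover some
language function, but the extent of recovery varies widely across
individuals. The question this package addresses is quantitative prognosis:
given the anatomy of an acute lesion and basic clinical covariates, how well
can language scores at later timepoints (1 month, 3 months, 1 year) be
predicted for an individual patient — and how much of that predictability
comes specifically from *where* the lesion is, as opposed to how large it is
or who the patient is demographically?

`mlsm` implements the full analysis as a reusable pipeline:

1. **Featurization.** Binary lesion masks, drawn on a shared voxel grid, are
   smoothed with a Gaussian kernel (FWHM 8 mm by default) and intersected
   with a labelled brain atlas. Each patient is reduced to a *lesion load
   vector* (LLV): one value per atlas ROI giving the proportion of that ROI
   that is lesioned, a number in [0, 1]. The reference parcellation has 150
   ROIs (123 grey-matter regions, 21 white-matter tracts, 6
   commissural-tract portions).
2. **Modelling.** Language scores (an overall score plus eight subdomain
   scores, each bounded on 0–10) are predicted by linear epsilon-insensitive
   support vector regression (SVR) from nested predictor families:
   - `llv`: 150 LLV entries + lesion extent (cm³) + age, sex, handedness,
     education, stroke type (156 columns);
   - `llv_ip`: the same plus the acute overall score ("initial
     presentation", IP; 157 columns), defined only at follow-up timepoints;
   - `reduced_no_llv` / `reduced_no_llv_no_extent` (and their `_ip`
     variants): the reductions that remove lesion location, then lesion
     extent, isolating the contribution of each.
3. **Evaluation.** Every model is assessed by leave-one-out cross-validation
   (LOOCV): each patient's score is predicted by a model that never saw any
   statistic of that patient. Accuracy is summarised by *prediction r²*,
   `1 − Σ(obs − pred)² / Σ(obs − mean(obs))²`, which can be negative, plus
   RMSE as a variance-independent companion.
4. **Weight mapping.** For interpretation, the LLV model is refit on all
   eligible cases, its lesion-load weights are thresholded at one standard
   deviation beyond the mean in the negative direction (ROIs where more
   damage predicts lower scores), and the surviving ROIs are painted back
   into brain space at their absolute weight magnitude.

A seeded synthetic-cohort generator supplies complete datasets — atlas,
contiguous lesions, covariates, longitudinal scores with missingness and
dropout — with known ground truth, so every stage is testable end to end
without any external data.

## The model and its assumptions

The SVR decision function is linear, `f(x) = w'x + b`, fit with the
epsilon-insensitive loss (residuals smaller than ε cost nothing) under a box
constraint C on the dual coefficients. The analysis assumes:

- **Additivity across regions.** The latent deficit is (approximately) a
  weighted sum of per-ROI lesion loads. There are no interaction terms;
  redundancy and disconnection effects are only captured insofar as they
  correlate with load patterns.
- **Bounded scores.** Raw predictions are capped to [0, 10] after fitting;
  capping can only reduce squared error when true scores lie in that range.
- **Independence of train and test.** All data-dependent preprocessing is
  nested inside the cross-validation loop (see below).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fwhm_mm` | 8 | mm | Gaussian smoothing of masks before LLV computation; softens boundary sensitivity of the parcellation |
| `box_constraint` (C) | 1 | — | SVR regularization; bounds each case's dual coefficient |
| `epsilon` | IQR(response)/13.49 | score units | insensitivity band, recomputed per training fold; 13.49 ≈ 2 × 6.745 converts an IQR into roughly twice a robust sigma |
| `gamma` | 1 | — | recorded for configuration fidelity; inert under a linear kernel (a note is logged rather than silently dropping it) |
| threshold | μ − 1σ | weight units | negative-weight selection for mapping; μ, σ over LLV weights only (population SD) |

## Numerical and design choices

- **FWHM to sigma.** `sigma_vox = fwhm_mm / (voxel_size_mm × 2√(2 ln 2))`
  per axis — the standard neuroimaging convention. The kernel is truncated
  at 4σ and renormalised to unit sum.
- **Boundary handling.** Smoothing pads with zeros: out-of-volume space is
  non-brain, so lesions touching the volume edge lose mass. On interior
  lesions the filter is mass-conserving (verified against a direct
  convolution oracle), and outputs are clipped to [0, 1] so LLV entries stay
  interpretable as proportions.
- **Order of operations.** Lesion extent is computed from the *binary*
  pre-smoothing mask; LLVs from the *smoothed* mask.
- **Binary enforcement.** Masks are thresholded at 0.5 on load, with a
  warning when stored values were not already {0, 1}.
- **Categorical encodings.** Single columns keep the feature count aligned
  with the predictor list: sex M=0/F=1; stroke type ischaemic=0/
  haemorrhagic=1; handedness as an ordinal R=1, A=0.5, L=0.
- **Scaling scope.** Min–max scaling parameters for the non-LLV columns are
  computed on the training fold only, applied to the held-out case with
  clipping to [0, 1]; constant training columns map to 0. The epsilon rule
  is likewise recomputed per fold. Nesting both inside LOOCV preserves
  train/test independence at the cost of slightly different scaling per
  fold. LLV columns are natively in [0, 1] and are never rescaled.
- **Quantile convention.** The IQR uses linear interpolation between order
  statistics (R type 7). Other environments' IQR conventions differ by
  O(ε) amounts; the 13.49 divisor is kept verbatim.
- **Determinism.** The SVR solver path (libsvm via e1071) is deterministic
  for fixed inputs; cases are processed in sorted patient-id order and the
  solution is row-order invariant (asserted in tests). Repeated pipeline
  runs under one config and seed are value-identical.
- **Degenerate inputs.** Constant responses give ε = 0 with a warning;
  constant weight vectors give an empty map selection with a warning rather
  than an error; cells that cannot be evaluated are recorded in the
  comparison grid with machine-readable reasons instead of aborting the run.
- **Full-sample refit for maps.** Weight maps come from a refit on all
  eligible cases rather than an average over LOOCV folds; the provenance is
  flagged in the weight table and run manifest.
- **Low-n flag.** Grid cells with fewer than 10 cases are flagged `low_n`,
  guarding against unstable r² in small demonstrations.

## What the synthetic generator emulates

The generator's defaults are the study conditions the pipeline is meant to
operate under:

- **Cohort.** 217 patients; independent follow-up dropout with retention
  102/217, 98/217 and 74/217 at 1, 3 and 12 months, independent of severity
  (so retained and dropped groups match in expectation — the no-sampling-bias
  property the analysis assumes).
- **Lesions.** Contiguous masks grown inside the labelled brain mask by
  uniform random frontier expansion, with sizes drawn from a log-normal
  matched to mean 53.6 and SD 60.4 cm³, truncated to 0.6–376.4 cm³. Growth
  absorbs sampled *batches* of the frontier (trimmed so the achieved count
  equals the target exactly); this keeps generation fast while preserving
  contiguity and seeded determinism. Vascular-territory realism is out of
  scope.
- **Atlas.** 150 contiguous parcels from farthest-point-seeded Voronoi
  assignment over an ellipsoidal mask, with the 123/21/6 tissue-class split.
  The default grid is 48³ voxels at 3 mm — coarse enough that a full cohort
  generates in seconds, fine enough that parcels average ≈ 7 cm³.
- **Scores.** Acute latent score = baseline (default 8.5) + Σ roi_weight ×
  LLV + Gaussian noise (SD 0.8). Five informative ROIs carry weights drawn
  from [−8, −4]; all others are 0. Follow-up latents are the acute latent
  pulled toward the ceiling of 10 by a recovery fraction, plus fresh noise;
  all scores clip to [0, 10]. Follow-up noise is smaller than acute noise
  (SD 0.5 versus 0.8): acute bedside evaluation in the first days
  post-stroke is the noisiest measurement setting, while chronic-stage
  assessments are calmer and more reliable. Recovery fractions are moderate
  and severity-dependent (severe patients recover a smaller fraction:
  0.15/0.25/0.35 versus 0.3/0.45/0.55 for mild, split at latent 5), which
  together keeps a substantial share of follow-up variance anatomy-driven —
  the regime in which lesion-based prognosis at one year is meaningful at
  all, and the one this analysis emulates. Because recovery acts on the
  noise-carrying acute latent, acute measurement noise propagates
  (attenuated) into follow-ups, as it would for any process anchored to the
  acute state. Since proportional recovery is disputed as an empirical law,
  the per-stratum fractions are fully configurable and both regimes are
  exercised in tests.
- **Subscores.** Correlated perturbations of the overall latent (target
  correlation 0.8) — a stand-in for testability only; no generative claim
  about subdomain structure is intended.
- **Untestables.** Patients with acute latent below 1.0 become untestable
  with probability 0.9: acute overall recorded as 0 (maximally impaired),
  acute subscores missing — exactly the convention the featurization module
  must respect (they enter acute overall models with response 0 and no acute
  subscore model).
- **Size-only regime.** In `truth_mode = "size"` every ROI's weight is
  −`size_slope` × its volume in cm³, making the deficit proportional to
  total lesioned volume, so lesion *extent* carries all the signal and the
  LLV family's advantage should vanish. This is the control condition for
  the full-versus-reduced contrast. The slope default (0.03 per cm³) is
  deliberately chosen so even the largest lesion in the truncation range
  produces a deficit near the width of the score scale: a steeper slope
  floor-censors a visible fraction of the cohort, and the censoring kink is
  itself predictive structure that lesion extent alone cannot represent but
  a 150-feature model partially can — which would contaminate a control
  regime whose premise is that extent carries *all* the signal.

**What it does not emulate:** vascular lesion morphology, hemispheric
asymmetries of real anatomy, systematic covariate–outcome associations
(demographics are generated independently of outcome, consistent with their
minimal predictive utility in this setting), subscore-specific anatomy, or
measurement properties of real aphasia batteries. Passing tests on these
cohorts therefore demonstrate that the *pipeline machinery* is correct and
that the modelling recovers known structure under its own assumptions — not
that any particular accuracy level will transfer to clinical data.

## Problem sizes used in tests and the acceptance script

Property and recovery experiments use n = 300 patients on the default
48³ × 3 mm grid with 150 ROIs; unit tests use 20³–24³ grids with 8–20 ROIs
and 8–40 patients; oracle comparisons use ≤ 20³ volumes where brute-force
nested-loop references are exact and fast. The noise-ceiling benchmark
disables untestable-acute conversion (`untestable_prob = 0`) so the ceiling
`1 − Σ(obs − noiseless)²/Σ(obs − mean)²` is well defined from the
generator's own noiseless trajectories.

## Known limitations

- **Ceiling gap.** LOOCV prediction r² sits systematically ≈ 0.07–0.11
  below the oracle noise ceiling at the benchmark conditions: the
  epsilon-insensitive loss ignores small residuals and C = 1 shrinks large
  weights (fitted informative weights are roughly half their generative
  magnitude), both of which bias predictions toward the centre. This is a
  property of the prescribed estimator, not a defect of the implementation.
- **Weight-map identifiability.** At the fine 150-parcel default, smoothing
  and lesion contiguity correlate adjacent parcels; the 1-SD negative
  threshold then stays fully sensitive (all truly informative ROIs
  selected in every replicate tried) but admits spatially adjacent false
  positives. On coarser, identifiable parcellations (30 ROIs) the selection
  matches the ground truth almost exactly. Feature weights should be read as
  a preliminary map, not an inferential statement — no significance
  procedure for SVR weights is attempted.
- **LOOCV at small n.** Leave-one-out estimates are high-variance for small
  cells; the `low_n` flag marks them. The package intentionally offers no
  alternative resampling scheme.
- **Proportional recovery.** The generator's recovery model is a
  convenience parameterisation; it should not be read as endorsing a
  proportional-recovery law.
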