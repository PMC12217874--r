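---
title: "Transformer-based early warning scores on synthetic ED streams: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformer-based early warning scores on synthetic ED streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tewsr implements a transformer-based early warning score (TEWS) pipeline for
emergency-department (ED) deterioration prediction: a synthetic cohort
simulator, windowed preprocessing of irregular event streams, a single-head
transformer encoder risk model with class-weighted loss, a Modified Early
Warning Score (MEWS) baseline, threshold/alarm evaluation with patient-level
bootstrap uncertainty, Grad-CAM-style attribution, and transfer-learning
fine-tuning. This vignette documents the models and the decisions behind
every convention the code enforces.

## The prediction problem

For each ED visit, the pipeline asks at every prediction time point: will
this patient experience a given adverse event — vasopressor use, advanced
respiratory support, ICU admission, septic shock, or in-hospital cardiac
arrest — within the next 24 hours? The input at each time point is the most
recent 48 hours of vital-sign and laboratory measurements, resampled into
192 fifteen-minute bins over N variables (13 in the full feature set: SBP,
DBP, HR, RR, body temperature, SpO2, Hb, BUN, sodium, potassium, lactate,
arterial pH, bicarbonate; the first 6 in the vital-sign-only set), plus a
static vector (scaled age, sex, mode of arrival). One independent model is
fitted per outcome.

## The synthetic cohort generator

Real ED streams cannot ship with a package, so `generate_cohort()` simulates
visits whose statistical structure matches the development population the
method targets:

* **Prevalence.** Each patient experiences at least one adverse event with
  probability 0.037 (the development population's 3.7%).
* **Event types.** A primary type is drawn from a distribution proportional
  to the published counts (vasopressor 6,304; respiratory support 5,017; ICU
  admission 8,492; septic shock 4,124; cardiac arrest 548); secondary types
  are added independently so the marginal share of each type among
  adverse-event patients matches the published shares (40.7 / 32.4 / 54.9 /
  26.6 / 3.5%). Cardiac arrest therefore stays rare (~3.5% of event
  patients), exercising rare-event behaviour downstream.
* **First measurements.** Group-conditional (event / no-event) means and SDs
  follow the published population table for all 13 variables, and for age,
  sex and mode of arrival. Where a variable's mean sits within 3 SD of a
  physiological bound (lactate, BUN, potassium, SpO2, SBP in the event
  group), a Gaussian clamped to the valid range would bias the mean, so the
  generator draws from a moment-matched shifted gamma anchored at the nearest
  bound (mirrored for upper bounds such as SpO2's 100% ceiling). This keeps
  the group mean and SD exact while producing the right-skew typical of
  laboratory values. Elsewhere a clamped Gaussian is used (clamp bias below
  3e-4 SD).
* **Within-stay trajectories.** Measurements after the first follow an AR(1)
  mean-reverting walk around the first-measurement baseline (coefficient
  0.8, innovation SD 0.3 of the group SD). The first measurement equals the
  baseline exactly, so group-mean recovery holds by construction even when
  an event occurs shortly after arrival; the group-conditional baselines
  already encode pre-arrival deterioration.
* **Deterioration drift.** Event patients additionally carry a monotone
  linear ramp that starts 12 h before the (first) event and reaches, at the
  event, −1.5 SD for SBP and SpO2, +1.5 SD for HR and RR, and +2.0 SD for
  lactate (zero for the other variables), plateauing afterwards. This is the
  learnable temporal signal that makes a 24-h-ahead label predictable from
  the window; it is an artifact of the simulator, not an estimate from data.
* **Cadence.** Vitals recur every 30–60 min (uniform); each lab is drawn 0,
  1 or 2 times per stay (probabilities 0.2/0.4/0.4), the first draw shortly
  after arrival at its baseline value. Published sources describe ED
  sparsity without quantifying it; these cadences are stated assumptions,
  not calibrated values.
* **Length of stay.** Log-normal, median 6 h, log-SD 0.8, capped at 72 h,
  floored at 15 min. Event times fall at 30–95% of the stay.
* **Values** are rounded to 2 decimals and timestamps to whole seconds, so
  CSV round trips are exact and a fixed seed reproduces a byte-identical
  cohort.

What the simulator deliberately does **not** model: physiological coupling
between variables (only marginal structure plus drift), triage scales,
do-not-resuscitate exclusions, measurement batching around care events, or
informative missingness. Tests passing on this simulator therefore show
that the pipeline's mechanics and the model's capacity to exploit a
temporal deterioration signal are sound — not that the published
discrimination transfers to any real population.

## Preprocessing conventions

All conventions below are enforced by brute-force oracle tests.

* **Outlier filtering** drops (never edits) values outside each variable's
  clinically acceptable range; the closed interval keeps boundary values.
  The shipped ranges (e.g. SBP [30, 300] mmHg, HR [10, 300] /min, lactate
  [0.1, 30] mmol/L, pH [6.5, 8.0]) are package defaults, overridable in the
  variable table.
* **Scaling** is min–max onto [0, 1] using the *fixed clinical range*, not
  training-set extrema. Zero-imputation after normalisation collides with
  true minima under any min–max choice; fixed ranges at least make the
  collision auditable and let a fitted model be applied to external data
  with no stored scaler.
* **Windows** end at the prediction time `t` and cover `[t − 48 h, t)`,
  half-open, so a measurement exactly at the prediction time is excluded.
  Bin `k` (1…192) covers `[t − (193 − k)·15 min, t − (192 − k)·15 min)`;
  within a bin the latest measurement per variable wins, ties broken by
  input row order. Empty bins are 0 with an observation mask of 0; stays
  shorter than 48 h leave the leading bins imputed. Every window has exactly
  192 rows regardless of stay length.
* **Prediction grid.** Every `cadence_minutes` (default 15) from the first
  retained measurement to departure. The method's description fixes the
  window geometry but not the grid spacing; the acceptance harness uses 60
  min to keep runtimes modest.
* **Labels** are 1 iff the outcome's first event time lies in
  `(t, t + 24 h]` (half-open on the left, closed on the right). Windows at
  or after a patient's own event are excluded for that outcome — the model
  predicts onset, not presence — while windows remain eligible for other
  outcomes. An event stamped before arrival raises a data-integrity error.
* **Statics.** Age is min–max scaled on [19, 110]; sex is coded female = 1;
  mode of arrival ambulance = 1. The method's description is ambiguous about
  whether arrival enters the static vector (one section lists it, another
  describes a two-dimensional age/sex vector); it is included by default and
  switchable off (`include_arrival = FALSE`).

## The MEWS baseline

`mews_score()` applies the standard published MEWS bands for SBP, HR, RR,
temperature and AVPU (maximum total 14), shipped as a CSV so variants can be
dropped in. AVPU is not part of the modelled stream and defaults to "alert"
(0 points); unobserved components score 0 (the common operational
convention — both are explicit assumptions, as the source method states
neither). `mews_series()` carries the last observed raw value of each
component forward within the same half-open 48-h window and emits an alarm
at score ≥ 5.

## The transformer risk model

Architecture (pre-layer-norm residual blocks, single attention head):

1. The window `X` (192 × N) is linearly projected to `d_model` and scaled by
   √d_model — the standard transformer embedding scale, which keeps the
   measurement signal commensurate with the sinusoidal positional encoding
   added next. (Without this scale the positional encoding dominates the
   embedding and training stalls.)
2. Each of the `n_layers` encoder layers applies layer-normalised
   single-head self-attention and a two-layer feed-forward block
   (`d_ff = 2·d_model`, ReLU), each wrapped in a residual connection with
   inverted dropout (default rate 0.1) on the branch output.
3. The normalised encoder output is pooled to one vector: either the final
   time step (`pooling = "last"`, the package default — the most recent
   state drives deterioration risk) or a masked mean over time steps from
   the first observed bin (`pooling = "mean"`). On sparse ED windows the
   masked mean aggregates evidence across the whole observed span instead
   of relying on attention to route it into the final bin, and it is what
   the scaled-down study harness uses.
4. Statics pass through one fully connected ReLU layer (width `d_static`,
   default 16); the concatenation of pooled sequence state and static
   representation enters an affine map and a sigmoid, yielding a risk in
   (0, 1).

The published configuration is 4 layers, single head, `d_model = 512`,
T = 192, AdamW at learning rate 1e-4, batch size 1000, 200 epochs; these are
the `model_config()` defaults, and the full-size configuration is
constructed and executed forward in the test suite. Training at that size is
not a desk-scale exercise; the harness configuration is described below.

**Loss.** Class-weighted binary cross-entropy with probabilities clamped at
1e-7. The published weight pair (ω_pos = 5.495, ω_neg = 0.505) is stored
verbatim as the default. Note the pair is mutually inconsistent under the
balanced rule `w_c = N/(2 N_c)` that reportedly produced it (5.495 implies
≈9.1% positives, 0.505 implies ≈1.0%); `compute_class_weights()` implements
the balanced rule, documents the discrepancy, and `loss_weights = "auto"`
uses it on the actual training labels.

**Optimisation.** AdamW (β = 0.9/0.999, ε = 1e-8) with decoupled weight
decay 1e-2 on weight matrices only (layer-norm parameters and biases are
excluded, as is standard). Dropout, weight decay and the learning-rate
schedule are unstated in the source; the defaults (0.1, 1e-2, constant
rate) are exposed in `model_config()`. After every epoch the validation
loss is computed with dropout off, and the parameters from the
best-validation-loss epoch are retained — mirroring validation-loss-based
model selection. The whole run is a deterministic function of the
configuration seed: parameter initialisation (Xavier uniform), batch order
and dropout masks all derive from it, and the dropout generator is
independent of R's global RNG.

**Implementation.** No deep-learning framework exists in this package's
dependency stack, and the encoder is the heart of the method, so the
forward pass and full analytic backpropagation are implemented in
RcppArmadillo. Samples are processed one at a time so all intermediates stay
cache-resident, large buffers are allocated once per batch, and attention is
kept in transposed layout so softmax reductions run down contiguous columns.
Correctness is anchored by a finite-difference test: every parameter
tensor's analytic gradient matches central differences to a relative error
below 1e-4 (observed ~1e-7) on both pooling paths, and the input gradient
used by Grad-CAM is checked the same way.

**Fine-tuning.** `fine_tune()` continues training *all* parameters on a
patient-level fraction (1% or 5% in the transfer experiments) of an external
cohort, at the same learning rate for one tenth of the original epochs, and
returns the final parameters (no checkpoint selection — the fine-tuning
samples are too small to carve a validation set from). Patients reserved for
external evaluation are excluded from sampling and any overlap is an error.

## Evaluation

The primary evaluation unit is the **patient visit**: a visit's score is the
maximum of its window scores (alarm semantics — an alarm anywhere during the
stay flags the patient) and its label is 1 if any eligible window is
labelled. The source tables' unit is unstated; per-window metrics remain
available for diagnostics by evaluating the window-level frame directly.

* **AUROC** is the Mann–Whitney concordance with ties counted 1/2, checked
  against exhaustive pair counting.
* **AUPRC** uses step-wise interpolation over recall; constant scores give
  the prevalence.
* The **alarm rule is score ≥ threshold** everywhere (consistent with
  "MEWS ≥ 5"). The operating threshold defaults to the **Youden index**
  maximiser over observed score values, ties broken toward the lower
  threshold (favouring sensitivity).
* **False alarms per 1,000 patients** = 1000 · FP / (evaluated visits).
* **Matched-sensitivity comparison**: the largest threshold whose
  sensitivity is at least the reference scorer's (the closest achievable
  from above), so two scorers are compared at a common sensitivity; the
  achieved sensitivity is reported alongside.
* **Risk tiers**: the low/intermediate cut is anchored at 90% sensitivity,
  the intermediate/high cut at 95% specificity; if the anchors cross, the
  tiers collapse with a warning.
* **Uncertainty**: percentile bootstrap over patient visits (resampling
  visits with all their rows, respecting within-visit correlation), 1000
  resamples by default, deterministic under a seed; undefined resamples are
  redrawn and counted. Scorer comparisons use a paired bootstrap of the
  AUROC difference with a t-statistic p-value (two-tailed); identical
  scorers give p = 1 by convention.

## Problem sizes in the test suite

The test suite exercises the full pipeline at sizes a single CPU handles in
minutes, chosen once as the package's study conditions:

* Generator recovery: 200,000 patients for the prevalence check (3 binomial
  SEs), 50,000 for the group-mean check (3 SEs of the mean).
* Learnability harness: 5,000 patients under the default study conditions,
  prediction cadence 60 min, vasopressor outcome; reduced encoder
  (`d_model = 32`, 2 layers, `d_ff = 64`, 20 epochs); training on every
  eligible window of event patients plus one window per event-free patient
  (event-free windows are heavily redundant); batch 64, learning rate 1e-3,
  masked-mean pooling, balanced class weights. The optimiser settings and
  pooling mode were selected on the *validation* partition only (the test
  partition was never consulted), consistent with validation-based model
  selection; at 20 epochs the published 1e-4 rate leaves the loss at its
  initialisation plateau, so the scaled harness uses the larger rate.
* Transfer property: a 3,000-patient external cohort with all group means
  shifted by +0.5 group SD; 5% fine-tuning sample; evaluation on the
  untouched 20% external test partition; tolerance 0.02 on the AUROC
  difference for sampling noise.
* Attribution recovery: drift confined to heart rate (magnitude 2 SD) in a
  1,500-patient cohort at 15% prevalence (power for the per-window
  true-positive analysis). Heart rate is used rather than a laboratory
  variable because labs are drawn at most twice per stay at the default
  cadence, so a lab cannot carry a within-window temporal signal for most
  windows.

## Grad-CAM adaptation

Grad-CAM was designed for convolutional maps; three adaptations are needed
for this encoder, all documented decisions:

* **Target layer.** Default is *input resolution*: the gradient of the
  pre-sigmoid risk score with respect to the raw (192 × N) window, so
  "channels" are named clinical variables. `mode = "layer"` instead targets
  the final encoder layer's normalised output (the closest analogue of the
  last convolutional layer) and projects the rectified time-saliency back
  onto observed input entries.
* **Weighting and rectification.** Channel weights are the time-averaged
  gradients; the weighted activations are rectified (negative contributions
  zeroed), so maps are nonnegative.
* **Aggregation.** A feature's attribution is its rectified saliency summed
  over time; `top_features()` ranks features by this aggregate (default top
  3, ties broken by feature order, zero-attribution features dropped).

Because maps in input mode are weighted by the input itself, attribution is
zero on imputed bins by construction. A degenerate model with all-zero
gradients yields an all-zero map with a warning and an empty feature list.

## Known limitations

* The simulator's marginal-plus-drift structure is far simpler than real ED
  physiology; discrimination numbers obtained on it say nothing about
  clinical performance.
* The printed class-weight pair is internally inconsistent (above); both the
  verbatim pair and the balanced rule are available, and which one the
  original fit actually used cannot be recovered from the text.
* Whether published metrics are per window or per visit is unstated;
  visit-level is this package's primary unit.
* Zero-imputation after min–max scaling conflates "missing" with "minimum";
  the observation mask is exposed but, matching the method, the default
  model does not consume it.
* Single-head attention only; multi-head and multi-task variants are out of
  scope.
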