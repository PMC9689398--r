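---
title: "Methods: CTG feature extraction, abstaining classification and LSTM forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTG feature extraction, abstaining classification and LSTM forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgforesee)
```

# Scope and data model

`ctgforesee` implements an integrated predictive-monitoring pipeline for
intrapartum cardiotocography: FIGO-style feature extraction from paired
fetal-heart-rate (FHR) and uterine-contraction (UC) signals, an abstaining
unanimous-vote ensemble for fetal-acidosis classification (cord pH < 7.2),
per-channel LSTM forecasting, and classification of the forecasted future.

A `ctg_record` holds both channels at a fixed 4 samples/second, an optional
cord pH, and a per-sample missing mask. An FHR value of 0 is treated as the
transducer-loss sentinel. Non-missing FHR must lie in [30, 250] bpm, UC must
be nonnegative. Throughout the package, intervals are half-open
`[onset, offset)` in 1-based sample indices; everything user-facing (CSV
sidecars, printed summaries) reports seconds.

# Signal conditioning

*Smoothing* is a centred moving average whose window shrinks at the edges.
The default window is 4 s (rounded to 17 samples for symmetry): long enough
to suppress beat-level jitter and sensor noise, an order of magnitude
shorter than the 15 s minimum event duration, so event morphology is
preserved. Missing samples are ignored inside the window rather than
propagated.

*Gap repair* linearly interpolates missing runs up to 15 s that are flanked
by observed samples, and leaves longer runs (and edge gaps) masked. The cap
equals the minimum event duration, so a repaired gap can never fabricate a
qualifying event on its own; linear interpolation cannot introduce extrema
beyond its anchors.

*Standardization* is the plain z-transform. For forecasting, the mean and
standard deviation are always estimated on the training split only and
reused unchanged downstream, so no information from the test or validation
periods leaks into the transform.

# Feature extraction

The baseline is estimated by an iterative fixed-point procedure: the initial
estimate `M` is the mean of all non-missing (smoothed) samples; candidate
events — maximal runs strictly above or below `M` with peak deviation
≥ 15 bpm and duration ≥ 15 s — are removed; the event-free mean `N`
replaces `M`; the loop repeats while `|N − M| > 0.5` bpm, with a cap of 50
iterations and an honest `converged` flag (oscillation on pathological
input is reported, not hidden). Event removal during the iteration uses
preliminary, untyped excursions; at least 2 minutes of usable signal are
required.

Typing is applied afterwards, in a strict precedence order that makes the
deceleration partition exhaustive and deterministic:

1. duration > 5 min → severe deceleration;
2. 2–5 min → prolonged deceleration (the band is closed: a tie at 2 min
   resolves to the shorter class, a tie at 5 min to prolonged);
3. onset strictly inside (peak, offset) of the paired contraction — the
   contraction with maximal overlap — and duration > 15 s → late;
4. drop from onset to nadir within 30 s → variable;
5. anything left → light.

Choices 3–5 resolve genuinely open definitional questions: clinical
guidelines describe variable decelerations as "abrupt", which is
operationalized here as ≤ 30 s to nadir; "light" is defined as the
complement class so the subtype counts always sum to the deceleration
count; positive excursions of 2–5 min mirror the prolonged-deceleration
band as prolonged accelerations.

Contractions are maximal UC runs exceeding resting tone by more than 10
units for 20–240 s. The tone is a rolling 10-minute 10th percentile
(evaluated every 30 s and interpolated): a low quantile tracks the resting
level robustly because contractions occupy well under 90% of any
10-minute window.

Histogram features use 1 bpm bins (matching FHR quantization); the mode is
the centre of the most populated bin (lowest on ties); peaks are local
maxima of the 3-bin-smoothed counts holding at least 5% of total mass, so
micro-texture does not masquerade as multimodality. Short-term variability
is the mean absolute successive difference of the *unsmoothed*,
gap-repaired signal over event-free samples: computing it after smoothing
would annihilate exactly the beat-to-beat alternation the statistic is
meant to measure (a ±2 bpm per-sample alternation has variability 4 bpm by
this definition, and nearly 0 after a 4 s moving average).

Cord pH below 7.2 labels a record acidotic (1); 7.2 itself is non-acidotic
(0). Count features that are nonzero in fewer than 3 cohort records are
pruned before classification — at a 94-record scale such features cannot
influence the fit — and Pearson correlations of constant columns are
flagged `NA` rather than silently zero-filled.

# Classification and the abstaining ensemble

Four base learners are supported: SVM (via `e1071`; radial-kernel width is
accepted in the `exp(−‖x−y‖²/2γ²)` parameterisation and converted
internally), random forest (`randomForest`), a single-hidden-layer neural
network (`nnet`, logistic hidden units, BFGS optimisation; the grid tunes
size and weight decay), and a k-means classifier (`stats::kmeans` on
features only, clusters mapped to their majority training label, ties
breaking toward the acidotic class because a false alarm is safer than a
miss). Hyperparameters are chosen by grid search under stratified 5-fold
cross-validation, maximizing mean CV accuracy; ties prefer the simpler
model, then grid order. Feature z-scoring is learned inside each training
fold. The winning configuration is refit on the full training split, and
its pooled out-of-fold predictions are summarised as accuracy, sensitivity,
specificity and precision (undefined ratios are `NA`, never 0).

The ensemble abstains: a class is output only on a unanimous vote, else
`"unsure"`. Abstention is a first-class outcome — combination accuracy is
always computed over classified samples only, and coverage (`n_classified`)
is reported beside it. Adding a member can only shrink coverage. The
coverage/accuracy trade-off across combinations is summarised by the
two-objective Pareto front (kept iff no other combination is at least as
good in both and better in one). `reference_combos()` bundles a published
benchmark of ten combinations as a worked example; applying the dominance
definition to it yields a four-point front — including one combination
that the benchmark's own narrative omits, which is why the package always
computes the front rather than hard-coding one.

Gaussian-noise oversampling (`oversample_gaussian`) augments a small cohort
by perturbing each row with per-column noise of `sigma_frac` × column-sd,
re-rounding count features; originals are kept first so class balance is
exact.

# The LSTM forecaster

The forecaster is implemented from the cell equations up (RcppArmadillo,
batched truncated backpropagation through time):

* gates `i, f, o = σ(x·U + y·W + b)`, candidate `Ĉ = tanh(x·U + y·W + b)`;
* state `C_t = f ∘ C_{t−1} + i ∘ Ĉ`, output `y_t = o ∘ tanh(C_t)`;
* the final hidden state feeds an optional dropout layer and a stack of
  linear dense layers ending in one forecast unit.

Biases are included (forget-gate bias initialized to 1, a standard aid to
gradient flow); input and recurrent weights start uniform in ±1/√H, dense
layers with Xavier bounds. Training is minibatch SGD with momentum 0.9,
learning rate 0.05, global gradient-norm clipping at 1.0, mean-squared
error loss, batch 64. All randomness (initialization, shuffling, dropout)
comes from a dedicated xorshift stream seeded from the spec, so a run is
bit-reproducible; divergence (non-finite loss) raises an error naming the
epoch.

The series is smoothed, split chronologically — the final 480 samples
(2 min) held out for validation, the remaining prefix 80/20 into train and
test, windows assigned by the index of their target — and standardized
with training statistics. Multi-step forecasts are recursive: each one-step
prediction is appended to the window and fed back (480 steps = 2 min,
960 = 4 min at 4 Hz).

One numerical subtlety drove a design choice. One-step test error is a poor
model-selection signal for recursive use: a model whose one-step residuals
are tiny can still drift over a 480-step rollout, and rollout quality
fluctuates substantially between epochs. Early stopping and best-weight
selection therefore monitor, by default, a recursive rollout over the tail
of the *test* split (`monitor = "recursive"`); the validation tail is never
touched during training. One-step monitoring remains available
(`monitor = "one_step"`). Reported errors are always in original signal
units: one-step RMSE/MAE on the test split and recursive RMSE/MAE over the
480-step validation tail.

Four stock architectures are provided (`forecaster_presets()`): lookbacks
1500/2000/1000/800 samples with 10 LSTM cells, dropout 0.1 where used, and
a dense stack ending in one unit. The `fast = TRUE` profile shrinks the
lookback to 64 samples so that desk-scale runs finish in minutes; the
layer stacks are unchanged. Per-record models are the design unit: one FHR
and one UC model per tracing; pooled cross-patient training is out of
scope.

# Future-state prediction

`predict_future_state` appends both channels' recursive forecasts to the
observed record and extracts features from the *extended* series before
classifying. Extraction on the full extended series (default) rather than
the forecast window alone is deliberate: a 2-minute window cannot host a
2–5 minute prolonged event, and the clinical question is "what will the
tracing look like then", which includes its history. `window = "forecast"`
exposes the alternative for comparison. Ensemble membership is
configurable and defaults to random forest + neural network. Forecast
samples are clamped to the physiological FHR range before re-extraction. A
zero horizon reduces exactly to classifying the observed record, which
pins the integration logic in tests.

# The synthetic generator

The generator emulates the statistical structure of a labor-ward cohort:

* baseline around 140 bpm (non-acidotic) or 135 bpm (acidotic) with a slow
  piecewise-linear wander (knots every 2 min, sd 2 bpm), plus
  between-record draws of the baseline (sd 4 bpm) and variability
  (sd 2.5 bpm) so that a cohort is heterogeneous the way real patients are
  and the classes overlap rather than separating trivially;
* short-term variability as a ±v/2 per-sample alternation (mean absolute
  successive difference exactly v), 10 bpm vs 4 bpm by class;
* events as raised-cosine humps/dips, except variable decelerations, which
  drop piecewise-linearly to the nadir within 5–12 s; event rates 12
  accel / 2 decel per hour (non-acidotic) vs 2 / 8 (acidotic), with the
  acidotic deceleration mix favouring late and variable subtypes;
* contractions as raised-cosine bumps (amplitude ≈ 30 units over a tone of
  8, 60–90 s, every ~180 s with jitter); late decelerations are planted
  with onset strictly after the paired contraction's peak and before the
  end of its detectable (tone + 10) interval, with guard bands of several
  seconds because a shallow deceleration's detected onset can drift;
* Gaussian sensor noise (sd 2 bpm on FHR, half on UC) and Poisson
  signal-loss gaps (6/hour, 3–20 s);
* cord pH from class-conditional truncated normals: acidotic
  N(7.05, 0.08) on [6.8, 7.19], non-acidotic N(7.30, 0.06) on [7.2, 7.5] —
  so labels recomputed from pH always match the generating class.

Every planted event satisfies its detector's thresholds with margin
(e.g. accelerations peak ≥ 20 bpm for 25–100 s; "light" decelerations last
75–110 s so their nadir time exceeds the 30 s variable-deceleration cut).
This yields a closure property that the tests exploit: with noise, drift
and between-record variation switched off, the detectors recover the
planted event set exactly, so any mismatch indicates a pipeline defect
rather than a data artefact. Cohorts derive one RNG stream per record from
the root seed and the record index, so they are reproducible and
insensitive to generation order; drawn plans that cannot fit the recording
are trimmed, while explicitly requested event counts that cannot fit raise
an infeasibility error.

What the generator does **not** emulate: physiologic feedback (no
mechanistic fetal model), sinusoidal patterns, maternal-heart-rate
crosstalk, drifting sensor gain, or the heavy-tailed artefact structure of
real transducers. Passing tests on synthetic cohorts therefore demonstrate
the correctness and internal consistency of the algorithms — not clinical
performance on hospital data, which the package makes no claim about.

# Problem sizes and runtime choices

The shipped studies are desk-scale by design: 94-record cohorts of
30-minute tracings for classification; 2-hour series with the
64-sample-lookback fast profile for forecaster sanity checks; showcase
forecasters trained for ~12 epochs inside `run_experiment`. These sizes
keep a full reproduction (test suite plus acceptance script) within a few
minutes on a single CPU while exercising every code path at realistic
signal lengths; all of them scale up by changing the corresponding
parameters.

# Known limitations

* The NN learner is a single-hidden-layer perceptron with logistic
  activation; grids over ReLU/tanh activations or alternative optimisers
  are not representable with this backend.
* The forecaster trains one model per record and channel; there is no
  pooled model, no exogenous-input conditioning (UC does not inform the
  FHR forecast), and recursive rollout error grows with horizon.
* Feature extraction assumes the 4 Hz sampling convention throughout.
* Abstention rates depend strongly on ensemble membership; the package
  reports coverage beside accuracy everywhere and leaves the choice of
  operating point to the analyst via the Pareto front.
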