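---
title: "Orientation-invariant transformations for wearable motion sensing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-invariant transformations for wearable motion sensing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oimotion)
```

## The problem

Window-based human-activity recognition pipelines extract per-axis features
from tri-axial accelerometer, gyroscope and magnetometer streams. Those
features silently assume that each sensor unit is mounted at a known, fixed
orientation: rotating a unit re-mixes the x, y, z axes and scatters every
per-axis statistic, so a classifier trained on correctly mounted sensors
degrades badly when users attach units at arbitrary orientations — which is
exactly what happens outside the laboratory.

`oimotion` removes the *absolute* orientation of each unit from the data
while preserving its *changes* over time (which carry activity information).
Two transformations are provided, applied per windowed segment during
pre-processing, so any downstream recognizer that consumes multi-channel
time series can be made orientation-invariant without other modification.

## The heuristic transform

Let $\vec v_n \in \mathbb{R}^3$ be the measurement at sample $n$, and
$\Delta \vec v_n = \vec v_{n+1} - \vec v_n$,
$\Delta\Delta \vec v_n = \Delta\vec v_{n+1} - \Delta\vec v_n$ its first and
second differences. The transform maps $\vec v_n$ to nine channels:

| channel | definition |
|---|---|
| $w_1,w_2,w_3$ | $\lVert\vec v_n\rVert,\ \lVert\Delta\vec v_n\rVert,\ \lVert\Delta\Delta\vec v_n\rVert$ |
| $w_4,w_5,w_6$ | angles between consecutive samples of $\vec v$, $\Delta\vec v$, $\Delta\Delta\vec v$ |
| $w_7,w_8,w_9$ | angles between consecutive rotation axes $\vec p_n=\vec v_n\times\vec v_{n+1}$, $\vec q_n=\Delta\vec v_n\times\Delta\vec v_{n+1}$, $\vec r_n=\Delta\Delta\vec v_n\times\Delta\Delta\vec v_{n+1}$ |

Each angle is $\cos^{-1}$ of the normalized inner product, set to $0$ when
either operand is the zero vector. Invariance under a constant proper
rotation $R$ follows from three facts: rotations preserve norms and angles,
differencing commutes with a constant rotation
($\Delta(R\vec v_n) = R\,\Delta\vec v_n$), and cross products map as
$R\vec a \times R\vec b = R(\vec a \times \vec b)$, so the rotation axes
rotate along with the data and the angles between them are unchanged. The
test suite verifies $T(RV) = T(V)$ to $10^{-8}$ over hundreds of random
blocks and rotations, and checks a closed form: uniform planar circular
motion $\vec v_n = (\cos\omega n, \sin\omega n, 0)$ gives the constant
channel vector
$(1,\ 2\sin\tfrac{\omega}{2},\ 4\sin^2\tfrac{\omega}{2},\ \omega,\ \omega,\ \omega,\ 0,\ 0,\ 0)$.

Numerical choices:

* **Common valid length $L' = L-4$.** $w_9[n]$ needs $\vec v_n$ through
  $\vec v_{n+4}$ — the deepest stencil. All nine channels are aligned to
  this common index range so they form a rectangular matrix, which the
  feature extractor requires. A segment must therefore contain at least 5
  samples.
* **Clipping.** The $\cos^{-1}$ argument is clipped to $[-1, 1]$; round-off
  can exceed the domain by about $10^{-16}$, and clipping guarantees finite
  output on any input.
* **Unnormalized rotation axes.** Only the directions of
  $\vec p, \vec q, \vec r$ matter for the angles, so they are not scaled to
  unit length.

Truncated 3- and 6-channel variants (`truncate_channels()`) and the
single-channel per-sample Euclidean norm (`euclidean_norm_transform()`, the
simplest proper invariant, identical to $w_1$) are provided; the norm
channel is computed by the same routine in both so they agree bit-for-bit.

## The SVD-based transform

For one unit and one segment, the sensor-type blocks
$V_1, \dots, V_S$ (each $3 \times L$) are scaled to comparable units,
concatenated as $\bar V = [\bar V_1 \cdots \bar V_S]$
($3 \times SL$), and factored by the compact singular value decomposition
$\bar V = U \Sigma W^\mathsf{T}$. The transform keeps
$\Sigma W^\mathsf{T} = U^\mathsf{T} \bar V$ — the segment re-expressed in
its own principal axes, with the absolute-orientation factor $U$ discarded.
Rotating the whole unit by $R$ replaces $U$ by $RU$ and leaves
$\Sigma W^\mathsf{T}$ unchanged *up to row signs*, because the decomposition
is unique only up to paired sign flips of the columns of $U$ and $W$.

Three design points:

* **Sign canonicalization.** Downstream moment features (mean, skewness)
  are not sign-invariant, so the transform must be a deterministic
  function: each output row is flipped so that its largest-magnitude entry
  is positive, ties resolved at the earliest column. How the original
  experiments resolved this ambiguity is not stated anywhere; this rule is
  this package's own choice and is flagged as such.
* **Per-sensor-type scales.** Each sensor type is divided by the population
  standard deviation of all its pooled values (`fit_sensor_scales()`), so
  that types with large numeric ranges do not dominate the joint
  decomposition. The scales are *part of the fitted model*: the
  transform is rotation-invariant for a fixed set of scales, but the pooled
  standard deviation itself shifts slightly when data are rotated (the
  pooled mean is not rotation-invariant). Rotation-transparency checks and
  deployments must therefore carry one fitted set of scales, exactly like
  any other trained normalization. In cross-validation the scales default
  to being fitted on the training folds (`scale_fit_mode = "train_only"`);
  a whole-dataset mode (`"all_data"`) reproduces pooled pre-processing at
  the cost of mild leakage.
* **Degenerate segments.** A rank-deficient segment makes the principal
  axes non-unique; sensor noise makes this a measure-zero event in
  practice, so it is reported as a warning, not an error, and the output is
  still returned.

The suite verifies the algebraic identity
$\Sigma W^\mathsf{T} = U^\mathsf{T}\bar V$, reconstruction, Frobenius-norm
preservation, non-increasing row variances, the row-sign structure of the
ambiguity before canonicalization, and invariance to $10^{-8}$ after it.

## Random-rotation simulation

Arbitrary mounting is emulated by drawing, for every segment and every
unit, a fresh rotation matrix
$R = R_x(\theta)\,R_y(\phi)\,R_z(\psi)$ with the three angles independent
and uniform on $[0, 2\pi)$, and left-multiplying all of that unit's blocks
by it — all sensor types of a unit share one physical orientation, hence
one matrix. Uniform Euler angles do not sample the rotation group
uniformly; they are used deliberately as the pinned simulation protocol.
The factor order is implemented exactly as written above even though the
yaw/pitch/roll naming in prose suggests the opposite convention: the
printed matrix is treated as ground truth.

## Features, normalization, PCA

Per channel, in fixed order: min, max, mean, skewness, kurtosis (population
moments, kurtosis non-excess); the biased mean-removed autocorrelation
$a(l) = \tfrac1L\sum_{n}(x_n-\bar x)(x_{n+l}-\bar x)$ at lag 0 (exactly the
population variance) and at lags $5, 10, \dots, 50$ that satisfy
$l \le L-1$; and the five largest one-sided DFT peak magnitudes with their
frequencies in Hz ($\text{bin}\cdot\text{rate}/L$), selected greedily
largest-first with a minimum pairwise distance of 11 bins, missing peaks
zero-filled.

Two conventions here are forced by arithmetic rather than taste. The
reference feature totals for five published sensor configurations (1170,
276, 234, 156, 78) are only reproduced if (a) two per-axis features beyond
the listed mean/variance/skewness/kurtosis/autocorrelation/DFT set are
included — min and max are adopted, the only pair consistent with all five
totals at once — and (b) the autocorrelation lag set is truncated by
segment length while the DFT peak slots are zero-padded to fixed width
(125-sample segments give 26 features per channel, 40-sample segments 23).
`feature_spec(include_minmax = FALSE)` selects the literal listed set, and
deliberately fails the count checks. Degenerate (zero-variance) channels
yield 0 for skewness and kurtosis.

Features are then min-max normalized to $[0,1]$ per subject and per column
(a subject-constant column maps to 0). Because each subject's own min/max
are used, this step precedes the train/test split by construction; that
mirrors the pooled pre-processing convention and its caveat is inherited
knowingly (the PCA and scale fit modes provide the leakage-free variants).
Finally PCA, fitted on the covariance of the training rows by default,
projects onto the `M = 30` leading eigenvectors; `scree()` exposes the
eigenvalue curve that motivates that default.

## Classifiers and cross-validation

Four classifiers with pinned settings, all tie-breaks deterministic by
class order:

* **Gaussian MAP (`bdm_*`)**: per-class maximum-likelihood mean and
  covariance, empirical priors, MAP rule. Non-positive-definite covariances
  are ridged by $10^{-6}\,(\mathrm{tr}\,\Sigma / M)\,I$, escalated tenfold
  until the Cholesky factorization succeeds, with an absolute ridge when
  the trace itself is zero.
* **k-NN** (`knn_predict()`): Euclidean metric, $k = 7$, vote ties broken
  by smallest mean neighbor distance.
* **One-vs-one RBF SVM** (`svm_train()`): $K(K-1)/2$ binary libsvm
  machines, $C = 40$, $\gamma = 0.2$, feature scaling off (inputs are
  already normalized). Fusion is pairwise max-vote with ties broken by
  accumulated $|$decision value$|$; a `"confidence"` fusion mode (single
  most confident machine decides) is selectable. Votes are read from each
  binary machine's predicted label because libsvm's decision-value sign
  follows its internal label order, which depends on training row order.
* **Single-hidden-layer perceptron** (`ann_train()`): sigmoid units,
  $H = \mathrm{round}_{\uparrow}\!\big(\tfrac12(\log_2 2K + 2K - 1)\big)$
  hidden neurons, one-hot targets, online back-propagation at learning rate
  0.3, weights initialized uniform on $[0, 0.2]$, per-epoch reshuffling from
  the seeded stream. Training stops at epoch $i$ once
  $\min\{E_{i-9},\dots,E_i\} > E_{i-10} - 0.01$ (so a flat error sequence
  stops at epoch 11), with a safety cap of 1000 epochs — whether the
  original training was online or batch, and any cap, is unstated, so
  online updates with a cap are pinned here as the package's choice.

Two validation schemes: seeded non-stratified **P-fold** ($P = 10$ by
default; sizes differ by at most one) and **leave-one-subject-out**, one
fold per subject, which probes cross-subject generalization and is the
harder scheme whenever subjects differ systematically.

`run_case()` wires the five experimental cases — reference, per-segment
random rotation, Euclidean norm, heuristic, SVD — through segmentation,
transformation, feature extraction, normalization, per-fold PCA and
classification, and returns per-fold accuracies with a pooled confusion
matrix whose trace identity (trace/total = pooled accuracy) is tested.

## The synthetic benchmark

`generate_dataset(synth_config())` produces the package's study conditions:
5 subjects × 6 activities × 2 units (accelerometer + gyroscope), 25 Hz,
60 s per recording — 360 five-second segments. Activities are harmonic-sum
archetypes: one static posture (pure gravity vector, magnitude 9.8, with a
direction drawn once per subject–activity), one slow movement, and two
pairs sharing a fundamental frequency (1.5 Hz and 2.5 Hz) whose members
differ only in how dynamic energy is distributed across axes — near
one-dimensional versus planar, and concentrated versus spread at matched
total power. Per-subject multiplicative amplitude/frequency jitter
(log-normal, sd 0.15 and 0.05) creates the subject-level shift that makes
leave-one-subject-out harder. Noise is Gaussian, sd 0.3 on inertial
channels.

The pair design is the point: fundamental frequencies and total power
survive random axis mixing, so those pairs are exactly what per-segment
random rotation destroys for a per-axis-feature classifier, while the
data's own principal axes (the SVD transform) recover the axis profile. On
these conditions the test suite asserts, at fixed seeds, that reference
accuracy exceeds the random-rotation case by at least 10 percentage points
(k-NN, P-fold), that the SVD case stays within 10 points of reference, and
that leave-one-subject-out does not beat P-fold.

What the generator does **not** model — and what passing tests therefore do
not show about real data: gyroscope channels are independent harmonic
processes, not derivatives of an orientation trajectory; there is no
soft-tissue artifact, sensor drift, within-segment orientation change, or
activity transition; amplitudes are in arbitrary units. The generator
validates the pipeline's mechanics and invariances, not field performance.

## Problem sizes and runtime envelope

All shipped checks are desk-scale by design: invariance properties use
hundreds of random blocks of up to 200 samples; end-to-end properties use
the default 360-segment benchmark; classifier oracles use a few hundred
rows at 30 dimensions. The complete suite runs in well under a minute on
one core.

## Known limitations

* The heuristic transform's angle channels are noise-amplifying for the
  higher differences ($w_8, w_9$); differences beyond second order are
  deliberately not offered.
* Sign canonicalization has measure-zero tie cases (exact ties in a row's
  maximal magnitude) where rotated and unrotated outputs can differ.
* Invariance of the SVD transform is per-segment; a sensor whose
  orientation drifts *within* a segment violates both transforms'
  assumptions (the heuristic one only needs constancy over its five-sample
  stencil).
* Per-subject normalization assumes each subject's full feature range is
  available; the train-statistics modes are the deployment-faithful
  alternatives.
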