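---
title: "Methods: plot-level soybean phenotyping from colored point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plot-level soybean phenotyping from colored point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Soybean breeding trials score hundreds of small plots for grain yield
(kg ha⁻¹) and lodging severity — the permanent displacement of stems from
vertical, graded on the odd scale 1 (none), 3, 5, 7, 9 (complete). UAV
photogrammetry can reconstruct each plot as a dense colored point cloud, and
the question this package addresses is how much of the yield and lodging
signal can be read directly from that cloud when its spatial structure
(x, y, z) and its visible-band spectral content (R, G, B and derived
vegetation indices) are fused at the data level and fed to a
permutation-invariant point-cloud network.

`soycloud` implements the full chain: cloud ingestion, cleaning and ground
removal, downsampling to a fixed point count, 13-channel feature fusion,
the two network families (single-task and multi-task), the four loss
regimes, micro-averaged cross-validated evaluation, and Global Moran's I
diagnostics of residual spatial structure. A synthetic canopy generator
stands in for field data so every stage is testable end to end.

## Preprocessing

Raw plot clouds carry reconstruction artifacts and the ground surface.
The pipeline applies, in order:

1. **Statistical outlier removal** — a point is dropped iff its mean
   distance to its k nearest neighbours (default k = 8) exceeds the global
   mean of that statistic by more than 2 SDs. No single filter is canonical
   for photogrammetric clouds; kNN-distance filtering was chosen because it
   is standard, parameter-light and easy to verify against a brute-force
   oracle.
2. **RANSAC ground fitting** — classic 3-point RANSAC (default 500
   candidate triples, inlier threshold 0.02 m, minimum support 50 points)
   followed by a total-least-squares refit on the winning candidate's
   inliers. The plot is treated as locally planar; sloped or terraced
   terrain is out of scope.
3. **Canopy separation** — points more than `margin` (default 0.05 m)
   above the plane are kept, and their heights above the plane are
   attached for the structure features.
4. **Exact-count downsampling** — voxel-grid pooling (default voxel
   0.01 m, refined when too coarse to supply at least half the target
   count) followed by uniform resampling to exactly one of the standard
   levels {256, 512, 1024, 2048, 3072, 4096}. Voxel pooling alone cannot
   hit an exact count, so the two-stage scheme makes the protocol's level
   comparison well defined.
5. **Input conditioning** — two modes. `unit_ball` is the classic
   PointNet convention (centre at the centroid, scale by the maximal
   radius). The pipeline default is `ground`: x and y are centred but z is
   the height above the fitted plane, all scaled by the maximal horizontal
   radius. The reason is physical: after the ground is removed, re-centring
   z per cloud erases absolute canopy height, which is the dominant yield
   signal; ground-referenced conditioning keeps it in the z channel while
   the fixed plot footprint still bounds coordinates near the unit ball.
   Both modes record their transform so metric heights stay recoverable.

All randomness flows from one master seed through a documented
purpose-string mixing rule (`derive_seed()`), so preprocessing, fold
assignment, initialization and augmentation are independently reproducible.

## Feature fusion

Each retained point contributes 13 channels in a fixed order:
(x, y, z, R, G, B, EXR, EXG, EXGR, MGRVI, RGRI, PPRb, VARI). Colors live on
[0, 1] — 8-bit inputs are divided by 255 at the file boundary — because the
ratio-type indices are scale-sensitive and the additive ones change by a
constant factor between color conventions; one canonical scale keeps
everything comparable. Ratio denominators are guarded by adding 1e-8 to
their absolute value with the sign preserved, so degenerate pixels yield
large-but-finite values rather than NaN. Two index quirks worth noting:
the red-green ratio index is implemented as R/G (its standard definition;
some summaries typeset the denominator ambiguously), and VARI is only
bounded by [-1, 1] on vegetation-like pixels (blue below both red and
green); elsewhere the guard keeps it finite but not bounded.

The classical plot-level feature table is also provided: means of all ten
indices (including WI, VEG and CIVE), six gray-level co-occurrence
statistics (32 quantization levels, distance 1, four angles averaged,
symmetric matrix — conventions this package fixes, since the statistics
themselves do not determine them), canopy height by DSM − DEM differencing with negatives clamped,
point-height mean/max/95% quantile (linear-interpolation convention),
2-D hull area and 3-D hull volume (both are reported because area and
volume are each standard), six density percentages (fraction of canopy
points above t × max height for t ∈ {0.5, 0.4, 0.3, 0.2, 0.1, 0.05} — the
relative-height reading of "density percentage"), and CIVE canopy cover.
Cover uses an Otsu threshold on the CIVE histogram rather than a fixed
cut, which makes the segmentation scale-invariant; vegetation sits below
the threshold because CIVE decreases with greenness.

## Architectures

Both families consume n × 13 clouds and end in three possible heads:
256×1 yield regression, 256×1 binary lodging logit, 256×5 five-class
logits.

* **SoyNet** — PointNet-basic without the T-Net alignment blocks: shared
  per-point MLPs 64-64 then 64-128-1024 (each dense + batch norm +
  LeakyReLU), max pooling to a 1024-d global feature, then a 512-256
  post-pooling MLP with LeakyReLU and dropout 0.6.
* **SoyNet-Res** — one CBR block lifts 13→64, then three residual CBR
  blocks staged 64→64→128→256. Each block raises the width by the
  expansion multiple k (default 2), applies BN + LeakyReLU, reduces back
  with a second dense + BN, adds the input (via a linear projection when
  widths differ), and applies a final LeakyReLU. Max or mean pooling gives
  a 256-d global feature, followed by a 256-256 MLP and dropout 0.6.
* **Multi-task (MDL)** — the SoyNet-Res backbone with both pooled paths:
  the mean-pooled vector feeds the regression head and the max-pooled
  vector the two classification heads, through a single shared 256-256
  post-pooling MLP. Sharing the trunk weights across both paths treats
  that MLP as a common feature extractor for all three heads; the trunk's
  batch-norm layers keep path-specific normalization statistics so each
  pooled distribution is standardized by its own moments.

LeakyReLU slope defaults to 0.01 and the residual expansion to k = 2; both
are recorded in `arch_spec()` and configurable. Batch normalization is used
in all per-point layers (the PointNet convention) and in the post-pooling
trunk; at the end of training the running statistics are refreshed by a few
forward passes at the final weights so eval-mode predictions reflect the
converged activation distribution.

The engine behind these models is implemented in compiled code
(RcppArmadillo) with hand-written backpropagation, templated on the
floating type: single precision for training speed, double precision
wherever numerically strict verification matters. Every test of the
forward pass compares the engine against an independent plain-R
re-implementation.

## Losses and training protocol

Yield regression uses the Huber loss with δ = 0.10 on z-scored targets
(training-fold mean and 1/n-SD only — validation folds are always
transformed with training statistics, and all reported errors are
back-transformed to kg ha⁻¹). δ is only meaningful relative to a target
scale; z-scoring is this package's choice and is pinned by the worked
example (a two-point fold (2000, 3000) maps to (−1, +1)). Classification
uses sigmoid + binary cross entropy (binary task) and softmax + cross
entropy (five-class task), with log arguments guarded at 1e-12.

Multi-task fusion is either a fixed weighted sum — weights keyed by task
name, never position, with the two published presets (1.0, 1.0, 0.1) and
(0.89, 0.10, 0.01) available — or homoscedastic-uncertainty weighting:
`sum_i exp(-2 s_i)/2 · L_i + s_i` with `s_i = log σ_i` learnable and
initialized to 1.0. Larger task uncertainty σ lowers the task's weight.

The optimizer is momentum SGD (momentum 0.9, initial learning rate 0.02,
weight decay 1e-4 on dense weights, batch size 25) with cosine decay to
1e-4 by default (step decay available) and no early stopping: the
final-epoch model is returned. Training-fold augmentation redraws every
epoch: geometry first (Gaussian jitter σ = 0.01 m clipped at 0.05 m,
full-circle rotation about the gravity-aligned z axis), then color (hue
±18°, saturation/value/contrast ±20%), with the vegetation-index channels
recomputed after the color jitter so spectral channels never drift from
the stored RGB. Rotations about arbitrary axes are available but off by
default since they would destroy the lodging geometry. Class imbalance is
handled by oversampling minority five-class grades with fresh augmentation
draws, applied to training folds only; requesting it on a validation fold
is an error by contract.

Cross-validation is stratified by five-class grade (with a warned fallback
to plain folds when a grade has fewer members than k); predictions from
all validation folds are pooled and metrics computed once on the pool
(micro-averaging).

## Evaluation

Regression reports RMSE, rRMSE (denominator: mean of the measured values
in the evaluated pool), MAPE (zero-valued measurements excluded with a
count), and the agreement statistic `r = 1 − sqrt(SSE/SST)`. That statistic
is *not* the Pearson correlation — it is 1 only for exact predictions and
can be negative — so the Pearson correlation is always reported alongside
under its own name and the two are never conflated. Classification reports
the confusion matrix, micro-averaged accuracy/precision/recall/F1 (which
coincide for single-label multiclass — a property test asserts this on
random confusion data), per-class precision/recall, and top-k accuracies
with probability ties broken toward the lower class index.

Spatial diagnostics compute Global Moran's I on cross-validated residuals:
signed error for yield, centred misclassification indicator for the
classification tasks. Weights default to k-nearest-neighbour (k = 8)
contiguity symmetrized by union and row-standardized (inverse-distance
with a cutoff is available); the scheme is recorded in every result so
tables are self-describing. Inference uses the normality approximation
(z-score and two-sided p) with an optional seeded permutation p-value;
the implementation is cross-checked in tests against brute-force double
sums and against `ape::Moran.I` (which uses the randomization variance —
the moments agree exactly, the spread approximately).

## The synthetic canopy generator

No deposited field data exists, so the generator defines the study
conditions. One plot is a 3.1 m × 1.9 m three-ridge footprint: a noisy
ground plane (roughness SD 0.012 m) plus ~60 plants whose stems tilt by a
grade-dependent mean angle (5°, 25°, 45°, 65°, 82° for grades 1–9, ±4°
per-plant jitter, shared lodging azimuth per plot) topped by ellipsoidal
crowns of colored points. Tilting reduces apparent canopy height by the
cosine of the tilt, which makes expected height monotone non-increasing
in grade — the geometric signal the classifiers must read. Canopy colors
are green-dominant and soil brown-dominant with overlapping channel
distributions, so CIVE-based segmentation is solvable but not trivial.

Yield is a linear function of realized structure:
`beta0 + beta_height · mean canopy height + beta_cover · cover −
beta_tilt · mean tilt + noise`, truncated at zero, with defaults
(1200, 1800 kg ha⁻¹ m⁻¹, 400, 4 kg ha⁻¹ deg⁻¹, noise SD 50 kg ha⁻¹) chosen
once so that the yield distribution matches the motivating trial's scale
(mean ≈ 2500, SD ≈ 480 kg ha⁻¹), canopy height dominates (as it does in
UAV phenotyping practice), and the noise is about 10% of the yield SD.
Fields lay plots on a grid, draw grades uniformly by default (so every
class is exercised; pass an imbalanced `grade_probs` to emulate a real
trial and exercise oversampling), scale plant count by the planting-density
code, and can inject a smooth Gaussian-random-field yield effect
(squared-exponential covariance, Cholesky draw) whose per-plot values are
returned as ground truth for the spatial tests.

What the generator does **not** emulate: photogrammetric reconstruction
artifacts (holes, ghost points, non-uniform density), within-canopy color
gradients and shadowing, occlusion between neighbouring plots, and any
genotype structure. Passing tests therefore demonstrate that the pipeline
recovers signal that is geometrically and spectrally present in a clean
canopy; they do not certify performance on real UAV reconstructions.

## Numerical choices and degenerate inputs

* Denominator guards (1e-8, sign-preserving) in all ratio indices; log
  guards at 1e-12 in the cross entropies.
* Constant images: GLCM correlation is returned as 1 with a warning;
  CIVE cover as 0 with a warning (no separable classes).
* Degenerate geometry: hull area/volume are 0 with a warning below 3/4
  affinely independent points; a single-point cloud normalizes with
  scale 1.
* The quantile convention is linear interpolation between order
  statistics; voxel grids hash on floor((p − min)/size) with a 1e-9 bias
  guard; probability ties in top-k break toward the lower class index.
* Plane normals are oriented with positive z; candidate triples that are
  collinear are discarded inside RANSAC.
* Training aborts with the offending epoch if the loss turns non-finite.

## Problem sizes used in the checks

The test suite runs entirely on generated data: unit tests use plots of a
few thousand raw points downsampled to 64–1024, and the end-to-end checks
use a 300-plot field at 512 points per plot trained for 60 epochs —
conditions chosen so the whole suite exercises every stage, including
three full trainings, at desk scale. `scripts/acceptance.R` re-runs that
end-to-end experiment from scratch at the same sizes.

## Known limitations

* Ground fitting assumes one locally planar ground surface per plot.
* LAS support covers uncompressed 1.x point formats 2/3; LAZ is not read.
* The GLCM operates on orthophoto crops, not on point clouds.
* The engine is CPU-only and single-threaded; it is sized for plot-level
  experiments (hundreds of plots), not for field-scale deep learning.
* With per-task pooling, the shared trunk's batch-norm keeps separate
  running statistics per pooled path; checkpoints store both.
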