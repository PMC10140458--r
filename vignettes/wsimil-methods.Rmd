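---
title: "Methods: weakly supervised biomarker prediction with attention-MIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised biomarker prediction with attention-MIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wsimil)
```

This vignette is the package's own account of what it computes, which
assumptions it makes, where the design was genuinely open, and what its
tests do and do not demonstrate.

## The weak-label setting

A whole-slide image (WSI) of H&E-stained tissue is orders of magnitude too
large to classify directly, and its biomarker label (MSI status, *BRAF*
mutation, ...) exists only per patient, not per region. The pipeline
therefore (i) cuts the slide into tiles of fixed *physical* size, (ii)
discards non-tissue tiles, (iii) maps each tile to a feature vector with a
frozen encoder, and (iv) learns a patient-level classifier over the *bag*
of tile vectors. The multiple-instance assumption is that only some tiles
("witnesses") express the phenotype; the model must find them without tile
labels.

## Tile preprocessing

**Tessellation.** The grid step in source pixels is `round(tile_um / mpp)`
with `tile_um = 256` µm; tiles are resampled to 512×512 px (bilinear).
Partial tiles at the right/bottom edges are discarded rather than padded,
so every tile covers the same physical footprint. Coordinates are 0-based,
top-left origin, half-open intervals — one fixed convention so heatmap
grids and tile archives can never be off by one.

**Tissue detection.** A tile is tissue when (a) the sum over RGB channels
of the per-channel median is below 660 (rejects glass/background: white is
765) and (b) it contains at least four *edge objects*. "Four edges" is not
a well-defined quantity at the pixel level; this package operationalizes it
as ≥ 4 connected components (8-connectivity) of Canny edge pixels, with the
Canny detector run on the luma grayscale (weights 0.299/0.587/0.114) at
σ = 1 and hysteresis thresholds at the 10th/90th percentile of the nonzero
gradient magnitude. Percentile thresholds adapt to contrast; a tiny
absolute floor guards the degenerate all-flat tile. Edge-object counting is
the nearest testable reading of the protocol and is validated against the
synthetic generator's ground-truth tissue masks (recall ≥ 0.9, background
false-positive rate ≤ 0.1 at the fixture's mask-fraction definitions of
tissue ≥ 0.5 and background ≤ 0.05).

**Blur.** The variance of the 3×3 Laplacian `[[0,1,0],[1,−4,1],[0,1,0]]`
(replicate borders) of the luma image, with 80 as the reference threshold.
The score *flags* blurry/homogeneous tiles; it never excludes them — the
protocol reports the below-80 fraction but keeps all tissue tiles.

**Macenko normalization.** Optical density is `−log10((I + 1)/256)` per
channel (the +1 avoids log 0 at I = 0). Pixels with any channel below the
OD floor β = 0.15 are discarded; the remaining OD cloud is projected on the
plane of its top two principal components (basis columns flipped so mean
projections are positive, which keeps the angle distribution away from the
atan2 branch cut); stain vectors sit at the 1st/99th percentile angles,
oriented to nonnegative OD, unit norm, hematoxylin first (the column with
the larger blue-channel component — hematoxylin is the blue-purple stain).
Robust maximum concentrations are the 99th percentile of per-pixel
nonnegative-least-squares concentrations (closed form for two stains:
solve the unconstrained 2×2 system, clamp to the axes by residual).
Normalizing a tile re-estimates its own stain matrix, rescales
concentrations by `ref_max / tile_max`, and reconstructs through the
*reference* stain matrix, clipped to 8 bits. A tile with fewer than 50
above-floor pixels is returned unchanged with a warning flag rather than
producing garbage. All constants (β, percentiles, I₀ = 256, minimum pixel
count) are the method's standard published defaults, surfaced as arguments.

**Model input.** Bilinear resize to 224 px, scale to [0, 1], per-channel
standardization with the ImageNet statistics mean (0.485, 0.456, 0.406)
and sd (0.229, 0.224, 0.225).

## Feature bags and clinical fusion

An encoder is a frozen contract `224×224×3 array → D-vector`. Shipping
self-supervised pathology encoders is out of scope; the package provides a
channel-mean toy encoder (D = 3, used by arithmetic oracles) and a seeded
random-projection encoder (average-pooled thumbnail times a fixed Gaussian
matrix) as a stand-in with the same interface. Bags persist in a
single-file container (RDS payload holding the K×D float matrix, K×2
integer coordinates and the identifying attributes); the round trip is
bit-lossless.

Clinical covariates enter as exactly four dimensions — sex (female 0 /
male 1), sidedness (left 0 / right 1), organ (colon 0 / rectum 1), age in
years. The declared input width of the multi-input model is D + 4, which
fixes the encoding to one binary dimension per two-level factor rather
than two-column one-hot blocks; the two encodings are linearly equivalent
for a first linear layer, and the +4 width is the documented contract.
Each dimension is mean-imputed and then centered/scaled with statistics
fitted **only on training-fold patients** (population sd; a constant or
all-missing field becomes constant 0 with a warning; an unknown level at
inference is treated as missing). A fully missing record therefore encodes
to the zero vector, and the clinical-only ablation (`zero_image_features`)
provably removes all image influence — a property test scores the same
clinical vector attached to two different random bags and requires
identical outputs.

## The attention-MIL head

Per tile, `h_k = Linear₂(ReLU(Linear₁(x_k)))` into 256 dimensions (both
layers carry biases; whether the second layer has one is not fixed by the
architecture description, and including it is the conventional default —
it is absorbed into the pooled summary and costs nothing). Attention
weights are `a_k = softmax_k(wᵀ tanh(V h_k))` with V ∈ ℝ¹²⁸ˣ²⁵⁶,
w ∈ ℝ¹²⁸, computed with max-subtraction; the bag summary is
`h_sum = Σ a_k h_k`; the classifier is BatchNorm1D → dropout (p = 0.5) →
linear (2 outputs) → softmax. With uniform attention the pooling reduces
exactly to the mean — the bridge to the mean-pooling baseline, asserted as
a cross-module test.

**Training** (defaults in `attmil_train_config()`): batches of 32
patients, 32 epochs, per-epoch uniform resampling of each bag to at most
K = 512 tiles, cross-entropy weighted by inverse class frequency, AdamW
(β₂ = 0.99, ε = 1e-5, decoupled weight decay 0.01 on weight matrices, not
on biases or batch-norm parameters), one-cycle cosine learning rate
lr_max/25 → lr_max = 1e-4 over 8 epochs → lr_max/10000 over the remaining
24, and β₁ cycled 0.95 → 0.85 → 0.95 with the same periodicity. Batch
normalization uses batch statistics in training (running statistics
updated with momentum 0.1, unbiased variance) and running statistics at
inference; dropout is inverted. The validation split is scored every epoch
for monitoring only — no early stopping, no model selection; the
final-epoch parameters are the model. One master seed fans out to
initialization, sampling and dropout streams. Parameter initialization is
the fan-in uniform scheme U(±1/√fan_in).

Bags of unequal size are processed per patient with gradients accumulated
to the declared batch size; the batch-norm forward/backward runs jointly
on the stacked summaries, so the computation is mathematically equivalent
to joint batching. The entire backward pass is hand-derived and checked
against central finite differences (relative error < 1e-8 per parameter
block) in the test suite.

**Per-tile scores.** The spatial "MSI-ness" maps require a per-tile
probability the bag-level architecture does not define. The package routes
each tile's embedding h_k through the classification block as a singleton
summary in inference mode; this definition coincides with the bag score
when K = 1 (asserted) and needs no extra parameters.

## The tile-classifier baseline

The comparison baseline fine-tunes a pretrained-style CNN on tiles that
inherit their slide's label, then mean-pools tile probabilities per
patient (probabilities, not logits — the aggregation named by the
protocol). Stage 1 trains only the replaced head for one epoch at 2e-3;
stage 2 unfreezes everything for 32 epochs with per-depth maximal learning
rates in equally spaced slices from 1e-3 (deepest group) to 1e-3/100
(shallowest), each following a one-cycle schedule (max/5 → max over 10
epochs → max/10000), β₁ cycled as above. The two stated learning rates are
reconciled as: 2e-3 is the stage-1 head rate, 1e-3 the stage-2 deepest
slice maximum — the only assignment consistent with both statements.
Training tiles are augmented with random rotations up to 360° (p = 0.75,
white fill) and vertical flips (p = 0.5); evaluation never augments.

The backbone is pluggable behind a forward/backward contract with named
parameter groups (shallow → deep) and an optional convolutional feature
layer. The default is a compact residual CNN (3×3 stem, one residual
block, global average pooling, linear head) that trains in seconds on one
CPU, so the suite needs no weight downloads; a flattened linear backbone
exists for logistic-regression oracles.

## Evaluation protocol

Stratified 5-fold cross-validation at the patient level: per class,
patients are shuffled and dealt round-robin, so per-fold class counts
deviate from exact proportionality by at most one patient. A 25%
validation subset (also stratified — the protocol says only "randomly
split off", and stratification makes small-fold monitoring less noisy) is
carved from each training portion. AUROC is the Mann–Whitney rank
statistic with half-credit ties; AUPRC uses step interpolation (the
average-precision convention), with the negative-class variant obtained by
inverting labels and scores. Replicate summaries report mean ± 1.96·sd/√n
(the CI construction is not pinned down by the source material; the
normal-approximation convention is documented and isolated in
`summarize_replicates()`). Predicted-positive is `score ≥ threshold`
(ties positive). The 95% in-domain sensitivity threshold is, per model,
the ⌈0.95·P⌉-th largest positive score on its own internal test fold,
averaged over the five models. External deployment scores the external
cohort with each fold model (AUROC replicates) and with the per-patient
mean of the five scores (threshold statistics). Model families are
compared with fixed-effects one-way ANOVA (for two groups the F statistic
is the squared pooled t, asserted to 1e-10); 2×2 odds ratios are ad/bc
with an optional Haldane 0.5 correction on zero cells. Internal test
metrics pool the five fold test sets' predictions before thresholding.

## Explainability

Attention heatmaps are min-max normalized per slide
(`(a − min)/(max − min)`); a constant attention vector (including K = 1)
degenerates to 0 with a warning rather than dividing by zero. Prediction
heatmaps place raw per-tile probabilities on the grid. Top-tile galleries
rank patients by bag score and tiles by attention × tile score, with tiers
cut at ⌈fraction·K⌉ and deterministic tie-breaking by (product, grid_row,
grid_col) so the selection is invariant to input order. Grad-CAM is
defined only for models with spatial feature maps (the tile CNN); for a
two-class head the channel weights are the spatially averaged gradients of
the target class's *softmax score*, which follows the discriminative
logit-difference direction — the raw-logit variant can be blind when a
class is encoded by the absence of activation, which a hand-constructed
brightness-detector network demonstrates in the tests. The map is the
rectified weighted activation sum, bilinearly upsampled and min-max
normalized; constant maps are flagged as degenerate. For the attention-MIL
path over precomputed features no gradient to pixels exists, and the
function refuses rather than fabricating saliency.

## Synthetic data: what it emulates, and what it does not

* `make_synthetic_slide()` — white background, pink textured elliptical
  blobs speckled with dark nucleus-like dots (so tiles contain edges), a
  ground-truth tissue mask, optional saturated pen strokes and blurred
  patches. It emulates the *QC-relevant* structure of a slide (brightness,
  edges, artifacts), not histologic texture.
* `make_he_tile()` — exact two-stain Beer–Lambert mixtures from known unit
  stain vectors: per-pixel mixing fraction Beta(0.5, 0.5) with a 10%
  exactly-pure fraction per stain, total magnitude Uniform(1.1, 2). The
  pure fractions exist because the percentile angle estimator can only
  recover directions it observes; the magnitude range keeps every pixel
  above the OD floor and away from the 8-bit quantization floor (magnitudes
  above ~2.5 render near-black pixels whose OD angles are dominated by
  integer rounding). The default eosin vector keeps its blue component
  below hematoxylin's, as real eosin does — the ordering rule depends on
  it.
* `make_mil_bags()` — the minimal Gaussian witness model: negatives are
  standard normal in D dimensions; positive bags shift ⌈πK⌉ witness tiles
  by μ along one unit direction. The direction is drawn from
  `direction_seed` (default: the cohort seed) so independently seeded
  cohorts can share one population — the natural train/external-validation
  setup. Desk-scale defaults: D = 64, K = 64, π = 0.1, μ = 3, 100 + 100
  patients, noise sd 1 — chosen so the Bayes rule is nearly perfect while
  one full reference training run takes well under a minute on one CPU.
* `make_clinical()` — label-conditional covariates: binary fields with
  configurable log-odds shifts (baselines 0.60 male / 0.35 right / 0.30
  rectum, near cohort frequencies), age normal (65, 10) with an optional
  mean shift, independent missingness. The default association preset
  (log-odds 2 on sidedness and organ) yields clinical-only AUROC ≈ 0.8 at
  n = 400.
* `make_score_table()` — binormal scores with separation
  `Δ = √2·Φ⁻¹(AUC)` mapped through the logistic function (monotone, hence
  AUROC-preserving); `AUC = 1` caps Δ at 6.

All generators are pure functions of their seeds. Passing tests on these
fixtures shows the *mechanics* are right — grid arithmetic, stain algebra,
optimization, statistics. It does not show that any encoder captures real
histologic signal, that real cohort AUROCs are reproduced (the clinical
cohorts are not public), or that attention maps would satisfy a
pathologist.

## Numerical choices and degenerate inputs

Softmax and attention use max-subtraction; log-loss clamps probabilities
at 1e-12; batch-norm ε = 1e-5 everywhere; a single-patient batch norm
degenerates gracefully (zero gradient). One-class training sets,
zero-tile slides, empty bags, all-missing clinical fields, all-equal
attention, zero-cell odds ratios and score tables with one class all
raise errors or flagged degenerate results rather than silent numbers.
Checkpoints and bag files are version-tagged single RDS archives.

## Problem sizes in the shipped checks

The test suite trains the full reference schedule on the 200-patient
witness preset (one recovery run plus three label-shuffled controls),
exercises reduced schedules (6 epochs, small dims) for the orchestration
tests, and keeps image fixtures at 24–128 px. The acceptance script runs
one recovery training, one shuffled control, two clinical-only trainings
at n = 400, the preprocessing QC battery and the statistic calibrations —
about two minutes on one CPU. The attention-localization check (witness
attention mass ≥ 2× the witness fraction) sits at the edge of what 224
optimizer steps produce on this preset: measured enrichment is 1.6–2.2×
across seeds with held-out AUROC ≥ 0.98, so that single assertion can fall
on either side of 2× depending on the seed while everything else is
stable.

## Known limitations

* No pyramidal slide formats; rasters must fit in memory with a known mpp.
* The shipped encoders are stand-ins; real deployments plug in a
  self-supervised pathology encoder behind `encoder_spec()`.
* Training is single-threaded R; it is sized for method verification at
  desk scale, not for cohorts of thousands of slides.
* Grad-CAM applies to the tile CNN only, and heatmap rendering
  (colormap, overlay alpha) is presentation, not contract.
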