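---
title: "slideheat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slideheat: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideheat)
```

This vignette explains the science inside `slideheat`: the models each stage
implements, the tunable parameters with their defaults and rationale, what
the synthetic generators do and do not emulate, and the numerical
conventions adopted where the underlying methods leave choices open. It
states no empirical result that the package's tests and acceptance script do
not themselves compute.

## 1. The pipeline at a glance

A gastric-lesion slide passes through: tissue RoI extraction → multiscale
patching → (optional) stain normalization → patch-level probabilistic
classification → malignancy-heatmap assembly → 44-feature heatmap
morphometry → random-forest slide classification. Clinical follow-up joins
the 44 features in the survival stage. Every stage is an exported function;
`run_pipeline()` wires them with a declarative config, one global seed
(fanned out per stage via `derive_seed()`, a small string-hash so stages
never share an RNG stream), JSON-line logs and a checksum manifest.

## 2. Tissue segmentation

Luminosity is the plain channel mean `(R+G+B)/3`; per-channel thresholding
was rejected as needless complexity since H&E background is near-achromatic.
`otsu_threshold()` maximizes between-class variance over all 256 cuts
(equivalently minimizes pooled intra-class variance) with ties broken toward
the smallest threshold, making the result deterministic on plateaus; tissue
is the dark side of the cut. The binary mask is closed with a disk
(dilation followed by erosion — asserted as an identity in the tests) and
connected regions below `min_area_fraction` of the tissue area are dropped.

Defaults: thumbnail downsample 32, `close_radius` 4 thumbnail pixels,
`min_area_fraction` 0.005. These are conventional values for ~40x scanned
material; none is critical, and all are exposed as arguments. A
single-valued thumbnail (blank slide) raises a "no tissue found" condition
rather than returning an empty mask.

## 3. The stain model

Per-pixel optical density follows Beer–Lambert, `OD = −log10(max(I,1)/I0)`,
and factorizes as `OD = C × S` with `S` the 2×3 matrix of hematoxylin and
eosin unit vectors and `C` the per-pixel concentrations. Estimation
(`estimate_stain_matrix()`) discards pixels whose OD is below `beta` in
every channel, projects the rest onto the top-2 eigenvectors of the OD
covariance, and takes the `alpha`/`1−alpha` percentiles of the polar angle
as the two stain directions — the classic robust-extremes construction.
Rows are sign-fixed nonnegative, unit-normalized, and ordered by the
blue-channel OD component (hematoxylin is the blue-heavy dye).

Numerical conventions and why:

* **Log base 10.** The base only rescales `C` and cancels in normalization.
* **White point `I0`.** Detected per image as the 99th luminosity
  percentile (clamped to [100, 255]) rather than fixed at 255. Scanner
  backgrounds routinely sit below 255; a fixed white point injects a
  constant gray OD offset whose off-plane component is silently dropped at
  reconstruction, visibly biasing both the eosin direction and the
  self-normalization error. `rgb_to_od()`/`od_to_rgb()` keep an explicit
  `I0 = 255` default for callers who want the fixed convention.
* **`beta = 0.15` OD, `alpha = 1%`,** robust maxima at the 99th
  concentration percentile: standard robust-extreme choices.
* **Degeneracy guards.** Fewer than 100 tissue pixels, an OD cloud whose
  second eigenvalue is below `2e-4` of the first (single-stain image), or
  angular spread below `1e-3` rad all raise a typed condition telling the
  caller to skip normalization; `normalize_to_reference()` then returns the
  input unchanged with a `normalization_failed` attribute and a warning.
* **Brightness standardization** (per-channel rescale of the 95th
  percentile to 255) runs before estimation only when the image is actually
  faded (upper-percentile luminosity under 200); unconditionally
  standardizing would brighten healthy images and break the near-identity
  of self-normalization.
* **Background pass-through.** Pixels with luminosity ≥ 240 are copied
  from the input; normalizing near-white pixels only amplifies noise.

Normalization solves the target's `C` by per-pixel least squares (negatives
clipped at 0), rescales each concentration channel by the ratio of
reference to target robust maxima, and reconstructs through the reference's
`S` and `I0`.

## 4. Patching and augmentation

Patches are cut on a grid per scale (default scales 768, 1024, 1495,
2048 px; stride = scale, i.e. non-overlapping, which is also the heatmap
setting) and resized to 299 px by exact area interpolation, implemented as
two dense overlap-weight matrix products — the box filter preserves the
mean exactly and introduces no ringing. A patch is emitted when its
footprint's tissue fraction reaches `min_tissue_fraction` (default 0.5);
labels come from a rasterized annotation mask with a purity rule (default
0.9: mixed footprints stay unlabeled and are excluded from training).

Augmentation draws an affine transform within bounded ranges — rotation
≤ 30°, shift ≤ 20% of the side, optional horizontal/vertical flips, shear
≤ 0.2 — and resamples bilinearly with reflection padding. Photometry is
never touched, so stain-normalized colors survive augmentation. All-zero
bounds give the exact identity (integer sampling positions), and flips are
involutions, both asserted in tests.

## 5. Patch classifier and saliency

Downstream stages depend only on the probability contract: a classifier
maps patches to `(p_normal, p_gastritis, p_cancer)` summing to 1 in fixed
class order, with malignancy probability `1 − p_normal`. The bundled
reference classifier is a multinomial logistic model (maximum likelihood =
cross-entropy) on the patch area-averaged to an 8×8×3 pixel grid. The
choice is deliberate: it is deterministic, trains in seconds on one CPU,
its accuracy on the procedural textures is high enough to exercise every
downstream stage, and its class scores are *linear* in the input — so the
saliency map (channel-max absolute gradient of the unnormalized class
score, min–max rescaled) has a closed form, back-projecting the weights
through the area-average operator. The tests verify the analytic gradient
against finite differences. A deep CNN can be slotted in by implementing
the same `predict` contract; nothing downstream changes.

Evaluation reports the 3-class confusion matrix, accuracy, per-class
sensitivity/specificity (`NA`, never 0, when a class is absent from the
evaluation set) and an ROC for the binary benign-vs-cancer reading obtained
by sweeping the malignancy threshold.

## 6. Heatmap assembly

The malignancy heatmap is defined pointwise as the maximum malignancy
probability over all patches containing the point. A finite raster needs a
cell convention: each cell (default 1024 level-0 pixels, the
non-overlapping heatmap patch size) takes the value at its center, with
footprints treated as half-open rectangles. Cells covered by no patch are
no-data (`NA`) — distinct from probability 0 — and cells outside tissue are
flagged by a companion grid. The max rule makes assembly monotone in the
prediction list and permutation-invariant; both are asserted
property-style, and the whole operation is checked cell-by-cell against a
brute-force double loop.

Heatmaps are exported as 16-bit single-channel TIFF (probability × 65535)
with a JSON sidecar carrying cell size, no-data cells and the tissue grid;
16-bit PNG export was rejected because the available PNG writer is 8-bit
only, and 8 bits cannot represent the 0.999/0.99 probability bins that the
morphometry distinguishes.

## 7. The 44-feature morphometry

Features 1–26 describe tumor regions — 8-connected components of cells at
or above a probability threshold (0.90 for counts/areas/perimeters/
eccentricities, 0.50 for the largest-region area/axis and extents).
Region properties: area = cell count; perimeter = boundary cell-edge count;
eccentricity and major-axis length from the equivalent ellipse of the
second central moments; extent = area over bounding-box area. Features
27–36 are statistics of the per-cell probabilities over tissue (mean,
population variance, SD, median, mode, min, max, range, sum, and the
average malignant probability); 37–44 are the proportions of tissue cells
in the right-closed bins (0.999, 1], (0.99, 0.999], (0.95, 0.99],
(0.9, 0.95], (0.8, 0.9], (0.7, 0.8], (0.6, 0.7], (0.5, 0.6].

Conventions adopted where definitions are open, all exercised by the
brute-force oracle tests:

* `≥` at every probability threshold, uniformly.
* Population (uncorrected) variance; skewness `m3/m2^1.5`; Pearson
  (non-excess) kurtosis `m4/m2²`; all statistics of an empty region set are
  0, and skewness/kurtosis of a zero-variance set are 0.
* Mode = the lower edge of the fullest right-closed percent bin, so a
  malignancy-free heatmap reports mode 0 (a midpoint convention would
  report 0.005 on an all-zero heatmap, which misreads "no signal").
* Areas and lengths are in heatmap cells; the cell size travels in the
  heatmap metadata. Proportion and probability features are
  scale-invariant; areas scale ×4 and lengths ×2 under grid doubling
  (asserted).
* Cells with no covering patch are excluded from the tissue set rather
  than imputed as 0.

Slide classification is a `randomForest` on the 44 features (500 trees,
`mtry = floor(sqrt(44))`, fixed seed). `split_cohort()` reproduces the
70/20/10 train/test/validation partition by rounding the train and
validation sizes and giving the remainder to test, which maps 763 slides to
534/153/76.

## 8. Survival analysis

Outcomes are discretized as died < 12 months, died in [12, 60), survived
≥ 60 (any status, since 60 observed months settle the class). Records
censored alive before 60 months are excluded from the 3-class forests —
their class is genuinely indeterminable — but retained for Kaplan–Meier and
log-rank, which handle right censoring natively. Three forests mirror the
clinical-only / heatmap-only / combined feature blocks with a 75/25 split.

Split-count importance counts the internal nodes splitting on each feature
across all trees (walked via `randomForest::getTree`), normalized to sum
to 1 and tagged clinical vs AI. Note the dilution behavior: when many
features share one latent signal the forest spreads its splits across them,
so shared signal depresses any single feature's rank — the
importance-recovery property is therefore tested against pure-noise
competitors (`informative_only` cohorts).

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (product-limit estimator, Greenwood variance with
log-scale 95% bands; `survdiff` chi-square with 1 df), wrapped in a compact
curve object; the tests pin the small-sample closed forms and a
hand-computed observed-minus-expected example. Median splits send records
equal to the median to the high group, matching the `x ≥ x̃` convention,
and also return the all-sample reference curve.

## 9. The synthetic generators

**Slides and patches.** Textures are procedural: glands sit on a jittered
lattice (pitch 24–30 px), each a ring of Gaussian nuclei around an
unstained lumen, with the ring radius deformed by a class-specific
amplitude — 0.06 for regular normal glands, 0.38 plus scattered
lymphocyte-like nuclei for gastritis, 0.80 with a strongly jittered,
crowded lattice for carcinoma. Per-pixel hematoxylin/eosin concentrations
map through `OD = C × S` and exponentiate to RGB, so the generating stain
matrix is exactly recoverable — the generative/analytic consistency the
stain tests rely on. Two realism constraints matter for estimation: dense
chromatin displaces cytoplasmic eosin (nucleus cores are hematoxylin-pure,
inter-gland stroma eosin-pure — without pure pixels the angular extremes
cannot reach the true stain directions), and chromatin density saturates
(`1.6 · tanh(c/1.6)`) so overlapping nuclei cannot push optical density
past what an 8-bit scanner resolves. The default background luminosity is
245, a typical scanner blank; the generating stain vectors are the
classical H&E pair (0.650, 0.704, 0.286) / (0.070, 0.990, 0.110).
Staining variability (`stain_jitter`) multiplies stain-vector components
and per-stain gains log-normally — multiplicative so eosin never becomes
blue-heavy, which would make the hematoxylin/eosin ordering rule genuinely
ambiguous, as it is in reality only for pathological dyes.

The stain-normalization benefit is studied at `stain_jitter = 0.25` with
128-px patches and 60 patches per class: severe but realistic lab-to-lab
variation, and patches large enough (~4 glands) for reliable per-patch
stain estimation. Smaller patches starve the estimator of pure-stain pixels
and weaker jitter leaves the raw classifier nearly unconfounded; both
regimes blur the contrast the study conditions are meant to exhibit.

**Cohorts.** Event times are exponential proportional hazards: hazard
`= baseline × exp(Σ coef · (x − mean(x)))` over named clinical and/or
heatmap-feature columns (centering makes the baseline the average
patient's rate). Defaults: n = 273, baseline 0.015/month, coefficients
0.20 per cancerous lymph node and 5.0 per unit of mean malignant
probability, 15% independent early censoring, staggered follow-up horizons
uniform on (12, 144) months. These were chosen once to yield a cohort with
all three outcome classes populated, roughly 40 months mean follow-up and
a 50–60% event rate — the shape of a long-running gastric-cancer follow-up
series. The 44-feature block derives from one latent tumor-burden variable
with per-feature noise, respecting the feature invariants (proportions in
[0, 1], counts integer); `informative_only = TRUE` replaces all
non-hazard features with independent noise for importance-recovery
studies.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: photorealistic histology (no nucleus-level
morphology, no mucin or necrosis), scanner artifacts (blur, stitching,
pen marks, coverslip edges), vendor format quirks, intra-slide stain
gradients, and biopsy-vs-resection differences in the survival features.
Accuracies on these textures say the pipeline's plumbing and statistics
are correct, not that any classifier generalizes to patient material.

## 10. Problem sizes

The test suite and acceptance script run everything at desk scale, chosen
so a full run fits comfortably on one CPU: slides of 192–512 px with
8–64 px heatmap cells, 40–100 patches per class at 48–128 px, 30 slides
through the full pipeline, cohorts of 200–600 patients, and 100-replicate
power studies. Each scaled-down size is stated where it is used; the
algorithms themselves are size-free.

## 11. Known limitations

* The reference classifier sees color and coarse texture only; it exists
  to exercise the probability contract, not to compete with a CNN.
* Macenko-style estimation needs both stains present; single-stain or
  near-white fields are (correctly) refused, and callers must handle the
  skip path.
* Region morphometry on very coarse heatmap grids (few cells) is noisy;
  perimeter in particular is a lattice quantity, not a geometric length.
* The survival stage models class membership, not time-to-event
  regression; no Cox model is provided.
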