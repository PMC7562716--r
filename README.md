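# slideheat

Desk-scale analysis of gastric-mucosa whole-slide images (WSIs): tissue
segmentation, stain normalization, multiscale patching, malignancy-heatmap
assembly, heatmap morphometry, random-forest slide classification, and
survival analysis — with a synthetic H&E slide and cohort generator so every
stage runs and is tested without any external data.

## Who this is for

Computational-pathology researchers and methodologists who need a tested,
fully reproducible reference implementation of the classic WSI
classification workflow for gastric lesions (normal mucosa → chronic
gastritis → intestinal-type carcinoma), and who want to study the pipeline's
statistical behavior under controlled, generatively known conditions.

## The method

1. **Tissue RoI.** A slide thumbnail is thresholded on luminosity with
   Otsu's criterion (tissue = the dark side), closed with a disk
   (dilation ∘ erosion) and cleaned of small regions.
2. **Stain model.** Per-pixel optical density obeys Beer–Lambert:
   `OD = −log10(I / I0)` and factorizes as `OD = C × S`, where `S` is the
   2×3 stain matrix (hematoxylin and eosin unit vectors in OD space) and `C`
   the per-pixel concentrations. `S` is estimated as the robust angular
   extremes of the OD cloud in the plane of its top-2 eigenvectors; an image
   is normalized to a reference by rescaling `C` to the reference's robust
   maxima and reconstructing through the reference's `S`.
3. **Patching.** Tissue is cut into square patches at multiple scales
   (768–2048 px, resized to 299), optionally stain-normalized and augmented
   by bounded affine transforms (rotation ≤ 30°, shift ≤ 20%, flips,
   shear ≤ 0.2 — never photometric).
4. **Patch probabilities.** A pluggable classifier maps each patch to
   `(p_normal, p_gastritis, p_cancer)`; the malignancy probability is
   `1 − p_normal`. The bundled reference classifier is a multinomial
   logistic model on area-downsampled pixels — small, deterministic, and
   with analytic gradients for saliency maps.
5. **Heatmap.** The slide's malignancy heatmap is
   `H(x, y) = max {Pr(p ≠ normal) : patch p contains (x, y)}`,
   rasterized on a cell grid (default 1024 px cells).
6. **44-feature morphometry.** From each heatmap: tumor-region counts,
   areas, perimeters, eccentricities and extents at probability thresholds
   0.90/0.50; probability statistics over tissue cells; and the proportions
   in the high-probability bins (0.999, 1], (0.99, 0.999], …, (0.5, 0.6].
7. **Slide classification.** A random forest (500 trees) on the 44 features.
8. **Survival.** Outcomes discretized as died &lt; 1 y / died 1–5 y /
   survived ≥ 5 y; random forests on clinical features, the 44 heatmap
   features, or both; split-count feature importance; Kaplan–Meier curves
   with Greenwood 95% bands and median-split log-rank tests
   (`S(t) = Pr(T > t | x ≥ x̃)` vs `Pr(T > t | x < x̃)`).

## Worked example

```r
library(slideheat)

# a synthetic slide: normal mucosa left, carcinoma right, with ground truth
gen <- generate_synthetic_slide(slide_spec(
  512, 512,
  list(list(class = "normal",
            vertices = cbind(c(20, 250, 250, 20), c(20, 20, 490, 490))),
       list(class = "cancer",
            vertices = cbind(c(270, 490, 490, 270), c(20, 20, 490, 490)))),
  seed = 3))

mask <- compute_tissue_mask(slide_thumbnail(gen$slide, 8), downsample = 8,
                            close_radius = 2)
mask
#> <tissue mask> 64 x 64 at downsample 8, threshold 144, tissue 81.8%

prof <- estimate_stain_matrix(gen$slide$data)
round(prof$S, 3)
#>                 R     G     B
#> hematoxylin 0.650 0.704 0.286
#> eosin       0.069 0.992 0.110

clf <- train_patch_classifier(generate_patch_set(40, patch_size = 64, seed = 42))
pt <- extract_patches(gen$slide, mask, scales = 64, out_side = 64,
                      min_tissue_fraction = 0.3)
probs <- predict(clf, lapply(pt, `[[`, "raster"))
hm <- assemble_heatmap(
  data.frame(x = sapply(pt, `[[`, "x"), y = sapply(pt, `[[`, "y"),
             w = 64, h = 64, prob = malignancy_probability(probs)),
  canvas_size = c(512, 512), cell_size = 64, tissue = mask)
hm
#> <heatmap 'slide'> 8 x 8 cells of 64 px, 0 no-data

fv <- extract_feature_vector(hm)
round(fv[c("tumor_area_fraction", "malignant_prob_avg", "bin_gt_0.999")], 3)
#> tumor_area_fraction  malignant_prob_avg        bin_gt_0.999
#>               0.656               0.765               0.547
```

The estimated stain rows sit within ~2° of the generator's hematoxylin
(0.650, 0.704, 0.286) and eosin (0.070, 0.990, 0.110) vectors. The
right-hand carcinoma region, plus boundary cells shared with the adjacent
normal region, drives roughly two thirds of the tissue cells past
probability 0.9.

A survival cohort with known hazard structure:

```r
co <- generate_cohort(cohort_spec(n_patients = 600, seed = 1))
fit <- fit_survival_rf(co, feature_set = "all", seed = 1)
fit
#> <survival RF (all features)> held-out accuracy 0.529 on 49 features
head(split_importance(fit), 3)
#>                   feature splits importance category
#> 46            bin_0.8_0.9    820 0.02689054       AI
#> 11 tumor_region_mean_prob    808 0.02649702       AI
#> 21             perim_kurt    748 0.02452942       AI

ms <- median_split_curves(co, "malignant_prob_avg")
c(chisq = ms$chisq, p = ms$p_value)
#>        chisq            p
#> 8.384416e+01 5.353548e-20
```

Heatmap-derived features fill the entire top-10 of the split-count
importance ranking here: the generator ties all 44 of them to one latent
tumor burden, so the forest spreads the shared prognostic signal across
them. A median split on the hazard-driving feature separates the
Kaplan–Meier groups decisively (log-rank χ² ≈ 84). To see one planted
feature rise to the top of the ranking against pure-noise competitors, set
`informative_only = TRUE` in `cohort_spec()`.

## Command line

A thin CLI over the same functions lives at `inst/cli/slideheat.R`
(subcommands `synth`, `mask`, `pipeline`, `km`); `run_pipeline()` +
`pipeline_config()` drive the same stages from R with resumable per-stage
outputs, a resolved-config dump and a checksum manifest.

## Limitations

Synthetic textures are procedural gland lattices, not photorealistic
histology; the reference patch classifier is a stand-in for a deep CNN at
desk scale; vendor WSI formats (SVS/NDPI/MRXS) are out of scope — slides are
plain PNG/TIFF rasters behind a pyramidal accessor. See the methods
vignette (`vignettes/slideheat-methods.Rmd`) for modelling assumptions and
parameter rationale.
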