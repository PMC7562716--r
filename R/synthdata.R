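# Synthetic H&E slide, patch and cohort generators with analytic ground truth.
#
# Tissue textures are procedural: glands sit on a jittered lattice, each gland
# is a ring of hematoxylin-rich nuclei around an eosin-poor lumen, and the
# ring radius is deformed with class-specific amplitude (regular glands for
# normal mucosa, deformed inflamed glands with scattered lymphocyte-like
# nuclei for gastritis, crowded irregular fused glands for carcinoma).
# Per-pixel hematoxylin/eosin concentrations are mapped through the
# Beer-Lambert stain model OD = C x S and exponentiated to RGB, so stain
# estimation on a generated image has an exact generating stain matrix to
# recover.

#' Default per-class texture parameters
#'
#' Gland geometry and staining intensity per lesion class. Units: `spacing`
#' (lattice pitch) and `radius` (gland ring radius) in pixels; `deform` is the
#' relative amplitude of the ring-radius perturbation; `n_nuclei` the nuclei
#' per gland ring; `nuc_sigma` the Gaussian nucleus radius in pixels;
#' `nuc_amp` the peak hematoxylin concentration per nucleus (OD units);
#' `eosin_base` the cytoplasm eosin concentration; `scatter` the density of
#' extra stroma-scattered nuclei per pixel.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_texture_params <- function() {
  list(
    normal    = list(spacing = 30, radius = 9,  deform = 0.06, n_nuclei = 14,
                     nuc_sigma = 1.7, nuc_amp = 0.95, eosin_base = 0.55,
                     scatter = 0.000),
    gastritis = list(spacing = 30, radius = 9,  deform = 0.38, n_nuclei = 18,
                     nuc_sigma = 1.7, nuc_amp = 1.00, eosin_base = 0.45,
                     scatter = 0.004),
    cancer    = list(spacing = 24, radius = 11, deform = 0.80, n_nuclei = 28,
                     nuc_sigma = 2.1, nuc_amp = 1.25, eosin_base = 0.38,
                     scatter = 0.002)
  )
}

#' Default generating stain parameters
#'
#' A conventional H&E stain matrix (rows = hematoxylin, eosin optical-density
#' unit vectors over R, G, B) and the background illumination used when
#' exponentiating concentrations to RGB.
#'
#' @return List with `S` (2 x 3 unit-row matrix) and `I0`.
#' @export
default_stain_params <- function() {
  S <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             eosin       = c(0.070, 0.990, 0.110))
  S <- S / sqrt(rowSums(S^2))
  list(S = S, I0 = 255)
}

#' Specify a synthetic slide
#'
#' @param width,height Level-0 slide size in pixels.
#' @param lesion_polygons List of `list(class =, vertices =)` entries; `class`
#'   in `lesion_classes()`, `vertices` an n x 2 level-0 (x, y) matrix. Later
#'   polygons overwrite earlier ones.
#' @param texture_params As `default_texture_params()`.
#' @param stain_params As `default_stain_params()`.
#' @param background_luminosity Background gray value (0--255).
#' @param seed Integer seed; identical spec + seed gives a bit-identical slide.
#' @return An object of class `slideheat_slide_spec`.
#' @export
slide_spec <- function(width, height, lesion_polygons = list(),
                       texture_params = default_texture_params(),
                       stain_params = default_stain_params(),
                       background_luminosity = 245, seed = 1) {
  stopifnot(is_count(width), is_count(height))
  for (i in seq_along(lesion_polygons)) {
    lp <- lesion_polygons[[i]]
    if (!is.list(lp) || is.null(lp$class) || is.null(lp$vertices))
      stopf("lesion_polygons[[%d]] must be list(class =, vertices =)", i)
    if (!(lp$class %in% lesion_classes()))
      stopf("lesion_polygons[[%d]] has unknown class '%s'", i, lp$class)
    v <- lp$vertices
    if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3)
      stopf("lesion_polygons[[%d]] vertices must be an n x 2 matrix, n >= 3", i)
    if (any(v[, 1] < 0) || any(v[, 1] > width) ||
        any(v[, 2] < 0) || any(v[, 2] > height))
      stopf("polygon %d lies outside the %d x %d slide bounds", i, width, height)
  }
  if (background_luminosity < 0 || background_luminosity > 255)
    stopf("background_luminosity must be in [0, 255]")
  structure(list(width = width, height = height,
                 lesion_polygons = lesion_polygons,
                 texture_params = texture_params, stain_params = stain_params,
                 background_luminosity = background_luminosity,
                 seed = as.integer(seed)),
            class = "slideheat_slide_spec")
}

# Smooth multiplicative noise field: bilinear interpolation of a coarse
# Gaussian grid (pitch `scale` pixels).
smooth_noise <- function(h, w, scale = 12, sd = 1) {
  gh <- ceiling(h / scale) + 1L
  gw <- ceiling(w / scale) + 1L
  g <- matrix(stats::rnorm(gh * gw, 0, sd), gh, gw)
  ry <- (seq_len(h) - 1) / scale
  rx <- (seq_len(w) - 1) / scale
  iy <- pmin(floor(ry), gh - 2); fy <- ry - iy
  ix <- pmin(floor(rx), gw - 2); fx <- rx - ix
  a <- g[iy + 1, ix + 1, drop = FALSE] * outer(1 - fy, 1 - fx) +
       g[iy + 2, ix + 1, drop = FALSE] * outer(fy, 1 - fx) +
       g[iy + 1, ix + 2, drop = FALSE] * outer(1 - fy, fx) +
       g[iy + 2, ix + 2, drop = FALSE] * outer(fy, fx)
  a
}

# Splat point amplitudes at their nearest pixel and blur with a unit-peak
# Gaussian: a fast separable stand-in for summing per-nucleus Gaussian blobs.
splat_gaussian <- function(h, w, xs, ys, amps, sigma) {
  M <- matrix(0, h, w)
  xi <- round(xs); yi <- round(ys)
  ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
  if (any(ok)) {
    acc <- rowsum(amps[ok], (xi[ok] - 1) * h + yi[ok])
    M[as.integer(rownames(acc))] <- acc
  }
  r <- ceiling(3 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  as.matrix(EBImage::filter2(M, outer(k1, k1), boundary = 0))
}

# Per-class concentration fields (hematoxylin, eosin) over an h x w canvas.
# Consumes the current RNG stream; callers seed it. Nuclei sit on gland rings
# (radius deformed with class-specific amplitude); dense chromatin displaces
# cytoplasm, so nucleus cores are hematoxylin-pure and the inter-gland stroma
# eosin-pure, as in real H&E material.
synth_concentrations <- function(h, w, class, tp) {
  p <- tp[[class]]
  ce <- p$eosin_base * (1 + 0.18 * smooth_noise(h, w, scale = 14))
  s <- p$spacing
  gx <- seq(-s / 2, w + s / 2, by = s)
  gy <- seq(-s / 2, h + s / 2, by = s)
  centers <- expand.grid(x = gx, y = gy)
  jit <- if (class == "cancer") 0.45 else 0.15   # fused, disordered lattice
  ncent <- nrow(centers)
  centers$x <- centers$x + stats::runif(ncent, -jit * s, jit * s)
  centers$y <- centers$y + stats::runif(ncent, -jit * s, jit * s)
  nxs <- nys <- amps <- vector("list", ncent)
  for (g in seq_len(ncent)) {
    n <- p$n_nuclei
    th <- 2 * pi * (seq_len(n) - 1) / n + stats::rnorm(n, 0, 0.08)
    freq <- sample(2:5, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    rr <- p$radius * (1 + p$deform * sin(freq * th + phase) +
                        stats::rnorm(n, 0, 0.05 + 0.1 * p$deform))
    rr <- pmax(rr, 1.5)
    nxs[[g]] <- centers$x[g] + rr * cos(th)
    nys[[g]] <- centers$y[g] + rr * sin(th)
    amps[[g]] <- p$nuc_amp * pmax(1 + stats::rnorm(n, 0, 0.15), 0.2)
  }
  n_scatter <- stats::rpois(1, p$scatter * h * w)
  if (n_scatter > 0) {
    nxs <- c(nxs, list(stats::runif(n_scatter, 1, w)))
    nys <- c(nys, list(stats::runif(n_scatter, 1, h)))
    amps <- c(amps, list(rep(0.9 * p$nuc_amp, n_scatter)))
  }
  ch <- splat_gaussian(h, w, unlist(nxs), unlist(nys), unlist(amps), p$nuc_sigma)
  # chromatin density saturates: overlapping nuclei must not drive the optical
  # density past what an 8-bit scanner resolves
  ch <- 1.6 * tanh(ch / 1.6)
  # chromatin displaces cytoplasm: suppress eosin where hematoxylin is dense
  ce <- ce * (0.05 + 0.95 * exp(-2.5 * ch / p$nuc_amp))
  # gland lumens are unstained
  lum_r <- max(1, floor(0.55 * p$radius))
  lum <- splat_gaussian(h, w, centers$x, centers$y, rep(1, ncent), lum_r / 2)
  ce[lum > 0.5] <- ce[lum > 0.5] * 0.2
  list(ch = pmax(ch, 0), ce = pmax(ce, 0))
}

# Map concentration fields to an 8-bit RGB array via OD = C x S,
# I = I0 * 10^(-OD).
concentrations_to_rgb <- function(ch, ce, S, I0) {
  n <- length(ch)
  od <- cbind(as.vector(ch), as.vector(ce)) %*% S
  img <- array(0, c(nrow(ch), ncol(ch), 3))
  for (k in 1:3) img[, , k] <- matrix(I0 * 10^(-od[, k]), nrow(ch), ncol(ch))
  round(clamp(img, 0, 255))
}

#' Generate a synthetic H&E slide with ground truth
#'
#' Paints each lesion polygon with its class texture (drawn generatively
#' through the stain model), leaving the rest of the canvas at the background
#' luminosity. Returns the slide together with the exact polygon annotations
#' and a class-coded level-0 label mask.
#'
#' @param spec A `slideheat_slide_spec`.
#' @return List with elements `slide` (`slideheat_slide`), `annotations`
#'   (`slideheat_annotations`) and `mask` (integer level-0 label matrix).
#' @export
generate_synthetic_slide <- function(spec) {
  stopifnot(inherits(spec, "slideheat_slide_spec"))
  set.seed(spec$seed)
  canvas <- array(spec$background_luminosity, c(spec$height, spec$width, 3))
  mask <- matrix(0L, spec$height, spec$width)
  labels <- vapply(spec$lesion_polygons, `[[`, "", "class")
  polys <- lapply(spec$lesion_polygons, `[[`, "vertices")
  ann <- annotation_set(labels, polys, slide_id = sprintf("synth-%d", spec$seed))
  for (i in seq_along(labels)) {
    inside <- polygon_fill(polys[[i]], spec$height, spec$width, 1)
    if (!any(inside)) next
    rows <- range(which(rowSums(inside) > 0))
    cols <- range(which(colSums(inside) > 0))
    h <- rows[2] - rows[1] + 1L; w <- cols[2] - cols[1] + 1L
    conc <- synth_concentrations(h, w, labels[i], spec$texture_params)
    rgb <- concentrations_to_rgb(conc$ch, conc$ce, spec$stain_params$S,
                                 spec$background_luminosity)
    sub <- inside[rows[1]:rows[2], cols[1]:cols[2]]
    for (k in 1:3) {
      chan <- canvas[rows[1]:rows[2], cols[1]:cols[2], k]
      chan[sub] <- rgb[, , k][sub]
      canvas[rows[1]:rows[2], cols[1]:cols[2], k] <- chan
    }
    mask[inside] <- match(labels[i], lesion_classes())
  }
  list(slide = slide_image(canvas, id = ann$slide_id),
       annotations = ann, mask = mask)
}

#' Generate a balanced labeled patch set
#'
#' Each patch is a full-canvas texture of one class rendered through the stain
#' model. `stain_jitter` perturbs the generating stain matrix and per-stain
#' concentration gains independently per patch, emulating slide-to-slide
#' staining variability (the condition under which stain normalization should
#' help a downstream classifier).
#'
#' @param n_per_class Patches per class (>= 1).
#' @param patch_size Square patch side in pixels.
#' @param classes Classes to generate (default all three).
#' @param texture_params,stain_params Generator parameters.
#' @param stain_jitter Nonnegative scalar; 0 means every patch shares the
#'   default stain matrix.
#' @param seed Integer seed.
#' @return List with `patches` (list of h x w x 3 arrays), `labels` (factor
#'   with levels in `lesion_classes()` order) and `stain_matrices`.
#' @export
generate_patch_set <- function(n_per_class, patch_size = 299,
                               classes = lesion_classes(),
                               texture_params = default_texture_params(),
                               stain_params = default_stain_params(),
                               stain_jitter = 0, seed = 1) {
  if (!is_count(n_per_class)) stopf("n_per_class must be a positive integer")
  stopifnot(is_count(patch_size), all(classes %in% lesion_classes()))
  set.seed(as.integer(seed))
  patches <- list(); labels <- character(0); mats <- list()
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      S <- stain_params$S
      gain <- c(1, 1)
      if (stain_jitter > 0) {
        # multiplicative per-component jitter keeps each dye in its plausible
        # cone (eosin never becomes blue-heavy), as real stain variation does
        S <- S * matrix(exp(stats::rnorm(6, 0, stain_jitter)), 2, 3)
        S <- S / sqrt(rowSums(S^2))
        gain <- exp(stats::rnorm(2, 0, stain_jitter * 1.5))
      }
      conc <- synth_concentrations(patch_size, patch_size, cl, texture_params)
      rgb <- concentrations_to_rgb(conc$ch * gain[1], conc$ce * gain[2],
                                   S, stain_params$I0)
      patches <- c(patches, list(rgb))
      labels <- c(labels, cl)
      mats <- c(mats, list(S))
    }
  }
  list(patches = patches,
       labels = factor(labels, levels = lesion_classes()),
       stain_matrices = mats)
}

# ---- survival cohort --------------------------------------------------------

#' Specify a synthetic survival cohort
#'
#' Event times follow a proportional-hazards model with exponential baseline:
#' the hazard for patient i is `baseline_hazard * exp(sum(coef * (x_i - mean(x))))`
#' over the named columns in `hazard_coefs` (clinical covariates and/or
#' heatmap features; covariates are centered so `baseline_hazard` is the
#' event rate of an average patient). Follow-up horizons are staggered
#' uniformly on (12, `max_follow`) months and an independent uniform
#' early-censoring mechanism fires with probability `censor_rate`.
#'
#' @param n_patients Cohort size.
#' @param hazard_coefs Named numeric vector of log-hazard-ratio coefficients;
#'   names refer to clinical columns (`age`, `macroscopic_type`,
#'   `distant_metastasis`, `infiltration_depth`, `lymph_nodes`) or 44-feature
#'   names (see `feature_names_44()`).
#' @param baseline_hazard Events per month at covariate value 0.
#' @param censor_rate Probability of independent early censoring, in [0, 1).
#' @param max_follow Maximum follow-up horizon in months.
#' @param informative_only If TRUE, heatmap features other than those named in
#'   `hazard_coefs` are pure independent noise (used to test importance
#'   recovery); otherwise all 44 features co-vary with a latent tumor burden.
#' @param seed Integer seed.
#' @return An object of class `slideheat_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 273,
                        hazard_coefs = c(lymph_nodes = 0.20,
                                         malignant_prob_avg = 5.0),
                        baseline_hazard = 0.015, censor_rate = 0.15,
                        max_follow = 144, informative_only = FALSE, seed = 1) {
  if (!is_count(n_patients, 2)) stopf("n_patients must be an integer >= 2")
  if (!all(is.finite(hazard_coefs))) stopf("hazard coefficients must be finite")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  structure(list(n_patients = n_patients, hazard_coefs = hazard_coefs,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 max_follow = max_follow, informative_only = informative_only,
                 seed = as.integer(seed)),
            class = "slideheat_cohort_spec")
}

#' Names of the clinical covariate columns
#' @return Character vector of length 5.
#' @export
clinical_covariates <- function() {
  c("age", "macroscopic_type", "distant_metastasis",
    "infiltration_depth", "lymph_nodes")
}

# Draw a plausible 44-feature block for n patients from a latent tumor burden
# u in (0, 1). Proportion features stay in [0, 1], counts are nonnegative
# integers. When informative_only, every feature not in `keep` is independent
# noise.
synth_features_44 <- function(n, u, informative_only = FALSE, keep = character()) {
  nm <- feature_names_44()
  F <- matrix(0, n, 44, dimnames = list(NULL, nm))
  prop <- function(center, sd) clamp(center + stats::rnorm(n, 0, sd), 0, 1)
  F[, "n_tumor_regions_large"] <- stats::rpois(n, 2.5 * u)
  F[, "tumor_area_fraction"] <- prop(0.85 * u, 0.05)
  F[, "largest_region_area_p50"] <- round(500 * u^2 * exp(stats::rnorm(n, 0, 0.3)))
  F[, "largest_region_major_axis_p50"] <- sqrt(pmax(F[, 3], 0)) * stats::runif(n, 1.1, 1.7)
  F[, "high_prob_cell_fraction"] <- prop(0.8 * u, 0.05)
  F[, "tumor_region_mean_prob"] <- prop(0.9 + 0.08 * u, 0.02)
  for (j in 7:26) F[, j] <- pmax(u * exp(stats::rnorm(n, 0, 0.4)) *
                                   c(80, 30, 200, 1, 3)[(j - 7) %% 5 + 1], 0)
  mp <- clamp(0.12 + 0.75 * u + stats::rnorm(n, 0, 0.04), 0.01, 0.99)
  F[, "prob_mean"] <- mp
  F[, "prob_var"] <- clamp(0.05 + 0.1 * u + stats::rnorm(n, 0, 0.02), 0, 0.25)
  F[, "prob_sd"] <- sqrt(F[, "prob_var"])
  F[, "prob_median"] <- clamp(mp + stats::rnorm(n, 0, 0.03), 0, 1)
  F[, "prob_mode"] <- clamp(mp + stats::rnorm(n, 0, 0.08), 0, 1)
  F[, "prob_min"] <- prop(0.02, 0.01)
  F[, "prob_max"] <- prop(0.9 + 0.09 * u, 0.02)
  F[, "prob_range"] <- pmax(F[, "prob_max"] - F[, "prob_min"], 0)
  F[, "prob_sum"] <- mp * round(stats::runif(n, 800, 1200))
  F[, "malignant_prob_avg"] <- clamp(mp + stats::rnorm(n, 0, 0.01), 0, 1)
  # bin proportions over (0.5, 1]: concentrate mass higher as burden grows
  bins <- matrix(stats::rgamma(n * 8, shape = 0.5 + outer(4 * u, seq(4, 0.5, length.out = 8))),
                 n, 8)
  bins <- bins / rowSums(bins) * clamp(0.8 * u + stats::rnorm(n, 0, 0.05), 0, 1)
  F[, 37:44] <- bins
  if (informative_only) {
    noise_cols <- setdiff(nm, keep)
    for (j in noise_cols) F[, j] <- stats::runif(n)
  }
  F
}

#' Generate a synthetic survival cohort
#'
#' @param spec A `slideheat_cohort_spec`.
#' @return A data frame with columns `id`, `time` (months), `status`
#'   (1 = died, 0 = alive at last contact), the clinical covariates and the
#'   44 heatmap feature columns.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "slideheat_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  clin <- data.frame(
    age = round(stats::rnorm(n, 61.9, 10.5)),
    macroscopic_type = sample(1:4, n, replace = TRUE, prob = c(0.15, 0.35, 0.35, 0.15)),
    distant_metastasis = stats::rbinom(n, 1, 0.15),
    infiltration_depth = sample(1:4, n, replace = TRUE, prob = c(0.15, 0.2, 0.35, 0.3)),
    lymph_nodes = stats::rpois(n, 3.2)
  )
  u <- stats::rbeta(n, 2, 2.6)
  feats <- synth_features_44(n, u, spec$informative_only,
                             keep = names(spec$hazard_coefs))
  X <- cbind(as.matrix(clin), feats)
  bad <- setdiff(names(spec$hazard_coefs), colnames(X))
  if (length(bad)) stopf("hazard coefficient names unknown: %s",
                         paste(bad, collapse = ", "))
  Xh <- X[, names(spec$hazard_coefs), drop = FALSE]
  Xh <- sweep(Xh, 2, colMeans(Xh))
  eta <- as.vector(Xh %*% spec$hazard_coefs)
  lambda <- spec$baseline_hazard * exp(eta)
  T_event <- stats::rexp(n, rate = lambda)
  horizon <- stats::runif(n, 12, spec$max_follow)
  time <- pmin(T_event, horizon)
  status <- as.integer(T_event <= horizon)
  cens <- stats::runif(n) < spec$censor_rate
  ct <- stats::runif(n, 0, time)
  time[cens] <- ct[cens]
  status[cens] <- 0L
  time <- pmax(time, 0.1)
  out <- data.frame(id = sprintf("pt%04d", seq_len(n)), time = time,
                    status = status, clin, check.names = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Write / read a cohort as CSV
#'
#' The column dictionary: `id`; `time` = follow-up duration in months;
#' `status` = 1 died / 0 alive at last contact; clinical covariates
#' (`clinical_covariates()`); then the 44 heatmap features
#' (`feature_names_44()`).
#'
#' @param cohort Data frame as returned by `generate_cohort`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
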