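# Stain-matrix estimation and stain normalization.
#
# Model: per-pixel optical density OD = -log10(I / I0) is linear in stain
# concentration, OD = C x S, where S is the 2x3 stain matrix (rows =
# hematoxylin, eosin unit vectors in OD space) and C the per-pixel 2-vector
# of concentrations. S is estimated as the robust angular extremes of the OD
# cloud projected on the plane of its two principal eigenvectors; an image is
# normalized by solving its own C, rescaling each concentration channel to a
# reference profile's robust maxima, and reconstructing through the
# reference's S.

#' Standardize image brightness
#'
#' Rescales each channel so its upper `percentile` maps to 255 (clipped to
#' [0, 255]); used against faded or dim slides before stain estimation. The
#' map is monotone per channel and a fixed point for images whose percentile
#' already sits at 255.
#'
#' @param img RGB array, values 0--255.
#' @param percentile Upper quantile used as the white point (default 0.95).
#' @return RGB array of the same shape.
#' @export
standardize_brightness <- function(img, percentile = 0.95) {
  check_rgb(img)
  out <- img
  for (k in 1:3) {
    v <- stats::quantile(img[, , k], percentile, names = FALSE)
    if (v < 1) next  # all-dark channel: no rescale rather than a blow-up
    out[, , k] <- clamp(img[, , k] * (255 / v), 0, 255)
  }
  out
}

#' RGB to optical density and back
#'
#' Beer-Lambert transform `OD = -log10(max(I, 1) / I0)` per channel and its
#' inverse `I = round(I0 * 10^(-OD))`. The roundtrip is exact for integer
#' intensities >= 1.
#'
#' @param img RGB array with values in 0--255.
#' @param I0 Background (incident) intensity, default 255.
#' @return `rgb_to_od`: array of per-pixel OD values; `od_to_rgb`: 8-bit RGB
#'   array.
#' @export
rgb_to_od <- function(img, I0 = 255) {
  check_rgb(img)
  if (min(img) < 0 || max(img) > 255) stopf("pixel values must be in [0, 255]")
  -log10(pmax(img, 1) / I0)
}

#' @rdname rgb_to_od
#' @param od OD array as produced by `rgb_to_od`.
#' @export
od_to_rgb <- function(od, I0 = 255) {
  round(clamp(I0 * 10^(-od), 0, 255))
}

# Flatten an h x w x 3 array to an n x 3 matrix of pixels.
as_pixel_matrix <- function(arr) {
  matrix(arr, prod(dim(arr)[1:2]), 3)
}

#' Estimate the stain matrix of an H&E image
#'
#' Pixels whose OD is below `beta` in every channel (background / near-white)
#' are discarded; the rest are projected onto the top-2 eigenvectors of the
#' OD covariance; the stain vectors are the directions at the `alpha` and
#' `1 - alpha` percentiles of the pixel angles in that plane, back-projected,
#' sign-fixed nonnegative and unit-normalized. The hematoxylin row is the one
#' with the larger blue-channel OD component. Robust per-stain maximum
#' concentrations are the `1 - alpha` percentile of the solved concentrations.
#'
#' @param img RGB array (0--255).
#' @param beta OD cutoff isolating tissue from background (default 0.15).
#' @param alpha Robust-extreme angular percentile (default 0.01).
#' @param I0 Background (incident) intensity. The default `NULL` detects the
#'   image's own white point as the 99th luminosity percentile (clamped to
#'   [100, 255]), which keeps the Beer-Lambert transform unbiased on scanners
#'   whose blank-glass background is darker than 255.
#' @param source Identifier recorded in the profile.
#' @return An object of class `slideheat_stain_profile`: list with `S`
#'   (2 x 3, rows hematoxylin/eosin), `max_concentrations` (length 2), `I0`,
#'   `source`.
#' @export
estimate_stain_matrix <- function(img, beta = 0.15, alpha = 0.01, I0 = NULL,
                                  source = "image") {
  check_rgb(img)
  if (is.null(I0))
    I0 <- clamp(stats::quantile(luminosity(img), 0.99, names = FALSE), 100, 255)
  od <- as_pixel_matrix(rgb_to_od(img, I0))
  keep <- od[apply(od, 1, max) >= beta, , drop = FALSE]
  if (nrow(keep) < 100)
    stopf("too few tissue pixels (%d) for stain estimation; skip normalization for this patch",
          nrow(keep), class = "slideheat_stain_error")
  ed <- eigen(stats::cov(keep), symmetric = TRUE)
  if (ed$values[2] < 2e-4 * ed$values[1])
    stopf("degenerate OD cloud (eigenvalue ratio %.2e): image appears single-stain",
          ed$values[2] / ed$values[1], class = "slideheat_stain_error")
  V <- ed$vectors[, 1:2, drop = FALSE]
  # deterministic eigenvector orientation
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  proj <- keep %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha, 1 - alpha), names = FALSE)
  if (diff(q) < 1e-3)
    stopf("degenerate angular spread (%.2e rad): image appears single-stain",
          diff(q), class = "slideheat_stain_error")
  back <- function(a) {
    v <- as.vector(V %*% c(cos(a), sin(a)))
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  }
  v1 <- back(q[1]); v2 <- back(q[2])
  # hematoxylin = the vector with the larger blue-channel OD component
  if (v1[3] >= v2[3]) S <- rbind(hematoxylin = v1, eosin = v2)
  else S <- rbind(hematoxylin = v2, eosin = v1)
  colnames(S) <- c("R", "G", "B")
  C <- solve_concentrations(keep, S)
  maxc <- apply(C, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  if (any(maxc <= 0)) maxc <- pmax(maxc, 1e-6)
  structure(list(S = S, max_concentrations = maxc, I0 = I0, source = source),
            class = "slideheat_stain_profile")
}

#' @export
print.slideheat_stain_profile <- function(x, ...) {
  cat(sprintf("<stain profile '%s'> I0 = %g\n", x$source, x$I0))
  print(round(x$S, 3))
  cat("max concentrations:", paste(round(x$max_concentrations, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Solve per-pixel stain concentrations
#'
#' Least-squares solution of `OD = C x S` per pixel; negative concentrations
#' are clipped to zero.
#'
#' @param od n x 3 matrix of OD pixels (or an h x w x 3 OD array).
#' @param S 2 x 3 stain matrix with independent rows.
#' @return n x 2 matrix of (hematoxylin, eosin) concentrations.
#' @export
solve_concentrations <- function(od, S) {
  if (is.array(od) && length(dim(od)) == 3) od <- as_pixel_matrix(od)
  G <- S %*% t(S)
  if (rcond(G) < 1e-10) stopf("stain matrix is rank-deficient")
  C <- od %*% t(S) %*% solve(G)
  colnames(C) <- c("hematoxylin", "eosin")
  pmax(C, 0)
}

#' Normalize an image's staining to a reference profile
#'
#' Estimates the target image's own stain profile, solves its concentration
#' map, rescales each concentration channel by the ratio of reference to
#' target robust maxima, and reconstructs RGB through the reference stain
#' matrix. Background pixels (luminosity >= `bg_luminosity`) pass through
#' unchanged. Brightness is standardized first only when the image is faded
#' (upper-percentile luminosity below `fade_threshold`). If estimation fails
#' the input is returned unchanged with attribute `normalization_failed` and
#' a warning.
#'
#' @param img RGB array (0--255).
#' @param reference A `slideheat_stain_profile` (or an RGB image, in which
#'   case its profile is estimated with the same parameters).
#' @param beta,alpha Estimation parameters as in `estimate_stain_matrix`.
#' @param bg_luminosity Pass-through threshold on (R+G+B)/3, default 240.
#' @param fade_threshold Trigger for brightness standardization, default 200.
#' @return RGB array of the same shape.
#' @export
normalize_to_reference <- function(img, reference, beta = 0.15, alpha = 0.01,
                                   bg_luminosity = 240, fade_threshold = 200) {
  check_rgb(img)
  if (!inherits(reference, "slideheat_stain_profile"))
    reference <- estimate_stain_matrix(reference, beta, alpha, source = "reference")
  res <- tryCatch({
    work <- img
    if (stats::quantile(luminosity(img), 0.95, names = FALSE) < fade_threshold)
      work <- standardize_brightness(work)
    prof <- estimate_stain_matrix(work, beta, alpha)
    od <- as_pixel_matrix(rgb_to_od(work, prof$I0))
    C <- solve_concentrations(od, prof$S)
    C <- sweep(C, 2, reference$max_concentrations / prof$max_concentrations, `*`)
    out_px <- od_to_rgb(C %*% reference$S, reference$I0)
    out <- array(out_px, dim(img))
    bg <- luminosity(img) >= bg_luminosity
    if (any(bg)) for (k in 1:3) {
      chan <- out[, , k]
      chan[bg] <- img[, , k][bg]
      out[, , k] <- chan
    }
    out
  }, slideheat_stain_error = function(e) {
    warning(sprintf("stain normalization skipped: %s", conditionMessage(e)),
            call. = FALSE)
    structure(img, normalization_failed = TRUE)
  })
  res
}
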