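# Multiscale patch extraction, patch labeling and affine augmentation.

#' Extract multiscale patches from a slide
#'
#' Lays a grid at each scale (stride = `stride_fraction` x scale), emits a
#' patch whenever the tissue fraction of its footprint reaches
#' `min_tissue_fraction`, and resizes every emitted raster to
#' `out_side` x `out_side` by area interpolation. This mimics viewing a glass
#' slide from low to high power: the four default scales capture lesion
#' contours down to gland-level texture.
#'
#' @param slide A `slideheat_slide`.
#' @param mask A `slideheat_tissue_mask` for the same slide.
#' @param scales Level-0 footprint sides in pixels.
#' @param stride_fraction Grid stride as a fraction of the scale (1 =
#'   non-overlapping, the heatmap setting).
#' @param out_side Output raster side (default 299).
#' @param min_tissue_fraction Minimum tissue fraction of the footprint.
#' @param rasters If FALSE, return footprints only (no pixel data).
#' @return List of patches; each is a list with `raster` (out_side^2 x 3
#'   array or NULL), `x`, `y`, `scale`, `label` (NA until labeled),
#'   `slide_id`.
#' @export
extract_patches <- function(slide, mask, scales = c(768, 1024, 1495, 2048),
                            stride_fraction = 1, out_side = 299,
                            min_tissue_fraction = 0.5, rasters = TRUE) {
  stopifnot(inherits(slide, "slideheat_slide"),
            inherits(mask, "slideheat_tissue_mask"))
  ds <- mask$downsample
  patches <- list()
  for (s in scales) {
    if (s > slide$width || s > slide$height) next
    stride <- max(1L, round(stride_fraction * s))
    xs <- seq.int(0L, slide$width - s, by = stride)
    ys <- seq.int(0L, slide$height - s, by = stride)
    for (y0 in ys) for (x0 in xs) {
      rows <- (floor(y0 / ds) + 1L):min(ceiling((y0 + s) / ds), nrow(mask$mask))
      cols <- (floor(x0 / ds) + 1L):min(ceiling((x0 + s) / ds), ncol(mask$mask))
      tf <- mean(mask$mask[rows, cols])
      if (tf < min_tissue_fraction) next
      raster <- NULL
      if (rasters) {
        raw <- read_region(slide, c(x0, y0), c(s, s), level = 0)
        raster <- resize_area(raw, out_side)
      }
      patches[[length(patches) + 1L]] <-
        list(raster = raster, x = x0, y = y0, scale = s, label = NA_character_,
             slide_id = slide$id)
    }
  }
  patches
}

#' Label a patch footprint from a rasterized annotation mask
#'
#' The label is the class occupying at least `purity_threshold` of the tissue
#' (non-background) pixels in the footprint; mixed footprints stay unlabeled
#' (`NA`) and are excluded from training.
#'
#' @param footprint Level-0 (x, y, w, h) of the patch.
#' @param label_mask Class-coded mask from `rasterize_annotations`.
#' @param downsample Downsample factor of `label_mask`.
#' @param purity_threshold Purity fraction required (default 0.9).
#' @return A class name from `lesion_classes()` or `NA_character_`.
#' @export
label_patch <- function(footprint, label_mask, downsample = 1,
                        purity_threshold = 0.9) {
  x0 <- footprint[1]; y0 <- footprint[2]; w <- footprint[3]; h <- footprint[4]
  rows <- (floor(y0 / downsample) + 1L):min(ceiling((y0 + h) / downsample), nrow(label_mask))
  cols <- (floor(x0 / downsample) + 1L):min(ceiling((x0 + w) / downsample), ncol(label_mask))
  sub <- label_mask[rows, cols]
  tissue <- sub[sub > 0L]
  if (!length(tissue)) return(NA_character_)
  counts <- tabulate(tissue, nbins = 3L)
  top <- which.max(counts)
  if (counts[top] / length(tissue) >= purity_threshold)
    lesion_classes()[top]
  else NA_character_
}

# Deterministic affine resample with reflection padding and bilinear
# interpolation. Angles in degrees; shifts in pixels; shear is the
# off-diagonal factor. Photometry is never altered.
apply_affine <- function(raster, rotation = 0, shift_x = 0, shift_y = 0,
                         flip_h = FALSE, flip_v = FALSE, shear = 0) {
  d <- dim(raster)
  h <- d[1]; w <- d[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- rotation * pi / 180
  # forward map: flip -> shear -> rotate -> translate (about the center)
  Fm <- diag(c(ifelse(flip_h, -1, 1), ifelse(flip_v, -1, 1)))
  Sh <- matrix(c(1, shear, 0, 1), 2, 2, byrow = TRUE)
  Rt <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  M <- Rt %*% Sh %*% Fm
  Minv <- solve(M)
  xo <- rep(0:(w - 1), each = h) - cx
  yo <- rep(0:(h - 1), times = w) - cy
  xi <- Minv[1, 1] * (xo - shift_x) + Minv[1, 2] * (yo - shift_y) + cx
  yi <- Minv[2, 1] * (xo - shift_x) + Minv[2, 2] * (yo - shift_y) + cy
  reflect <- function(u, n) {
    if (n == 1) return(rep(0, length(u)))
    period <- 2 * (n - 1)
    u <- abs(u) %% period
    ifelse(u > n - 1, period - u, u)
  }
  xi <- reflect(xi, w); yi <- reflect(yi, h)
  x0 <- pmin(floor(xi), w - 2); y0 <- pmin(floor(yi), h - 2)
  fx <- xi - x0; fy <- yi - y0
  i00 <- x0 * h + y0 + 1
  out <- array(0, d)
  n <- h * w
  for (k in seq_len(d[3])) {
    ch <- raster[, , k]
    v <- ch[i00] * (1 - fx) * (1 - fy) + ch[i00 + 1] * (1 - fx) * fy +
      ch[i00 + h] * fx * (1 - fy) + ch[i00 + h + 1] * fx * fy
    out[, , k] <- matrix(v, h, w)
  }
  out
}

#' Randomly augment a patch raster
#'
#' Draws an affine transform within the stated bounds -- rotation up to
#' `rotation` degrees, shifts up to `shift` of the side, optional horizontal /
#' vertical flips, shear up to `shear` -- and resamples with reflection
#' padding. Brightness and contrast are never altered. Deterministic under
#' `seed`.
#'
#' @param raster h x w x 3 patch raster.
#' @param params List of bounds: `rotation` (degrees, default 30), `shift`
#'   (fraction of side, default 0.2), `flip` (logical, default TRUE), `shear`
#'   (default 0.2). All-zero bounds give the identity transform.
#' @param seed Integer seed.
#' @return Augmented raster of the same shape.
#' @export
augment_patch <- function(raster, params = list(rotation = 30, shift = 0.2,
                                                flip = TRUE, shear = 0.2),
                          seed = 1) {
  check_rgb(raster, "patch raster")
  defaults <- list(rotation = 30, shift = 0.2, flip = TRUE, shear = 0.2)
  params <- utils::modifyList(defaults, params)
  set.seed(as.integer(seed))
  side <- dim(raster)[1]
  rot <- stats::runif(1, -params$rotation, params$rotation)
  sx <- stats::runif(1, -params$shift, params$shift) * side
  sy <- stats::runif(1, -params$shift, params$shift) * side
  fh <- isTRUE(params$flip) && stats::runif(1) < 0.5
  fv <- isTRUE(params$flip) && stats::runif(1) < 0.5
  sh <- stats::runif(1, -params$shear, params$shear)
  apply_affine(raster, rot, sx, sy, fh, fv, sh)
}
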