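# Tissue/background separation: Otsu threshold on luminosity, morphological
# close, small-region removal.

#' Otsu threshold of a 256-bin gray histogram
#'
#' Returns the cut t (0--255) maximizing the between-class variance when gray
#' levels <= t form one class and levels > t the other (equivalently,
#' minimizing the pooled intra-class variance). Ties are broken by the
#' smallest t.
#'
#' @param histogram Numeric vector of 256 counts for gray levels 0..255.
#' @return Integer threshold in 0..255.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256 || any(histogram < 0))
    stopf("histogram must be 256 nonnegative counts")
  occupied <- which(histogram > 0)
  if (length(occupied) < 2)
    stopf("degenerate histogram: fewer than two occupied gray levels",
          class = "slideheat_degenerate")
  p <- histogram / sum(histogram)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_total <- mu[256]
  # between-class variance for cut t = level index - 1 (class 0: levels <= t)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_total * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  t <- which.max(sigma_b) - 1L  # which.max takes the first (smallest) maximizer
  as.integer(t)
}

#' Compute a tissue mask from a slide thumbnail
#'
#' Luminosity (R+G+B)/3 is thresholded with Otsu (tissue is the dark,
#' below-threshold side, background the bright white side), the binary mask is
#' closed with a disk (dilation followed by erosion), and connected regions
#' smaller than `min_area_fraction` of the total tissue area are dropped.
#'
#' @param thumbnail RGB array (0--255), typically from `slide_thumbnail()`.
#' @param downsample The factor the thumbnail was taken at (recorded only).
#' @param close_radius Disk radius of the morphological close, in thumbnail
#'   pixels.
#' @param min_area_fraction Regions with area below this fraction of the total
#'   tissue area are removed.
#' @return An object of class `slideheat_tissue_mask`: list with `mask`
#'   (logical matrix), `downsample`, `threshold`, `close_radius`,
#'   `min_area_fraction`.
#' @export
compute_tissue_mask <- function(thumbnail, downsample = 32, close_radius = 4,
                                min_area_fraction = 0.005) {
  check_rgb(thumbnail, "thumbnail")
  gray <- floor(clamp(luminosity(thumbnail), 0, 255))
  hist256 <- tabulate(gray + 1L, nbins = 256)
  t <- tryCatch(otsu_threshold(hist256),
                slideheat_degenerate = function(e)
                  stopf("no tissue found: thumbnail luminosity is single-valued",
                        class = "slideheat_no_tissue"))
  mask <- gray <= t
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    m <- EBImage::erode(EBImage::dilate(mask * 1, brush), brush)
    mask <- m > 0.5
  }
  if (any(mask) && min_area_fraction > 0) {
    lab <- label_connected(mask)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area_fraction * sum(mask))
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask))
    stopf("no tissue found after filtering", class = "slideheat_no_tissue")
  structure(list(mask = mask, downsample = downsample, threshold = t,
                 close_radius = close_radius,
                 min_area_fraction = min_area_fraction),
            class = "slideheat_tissue_mask")
}

#' @export
print.slideheat_tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue mask> %d x %d at downsample %d, threshold %d, tissue %.1f%%\n",
              nrow(x$mask), ncol(x$mask), x$downsample, x$threshold,
              100 * mean(x$mask)))
  invisible(x)
}

# 8-connected component labeling of a logical matrix. Small grids only
# (thumbnails and heatmap lattices); plain flood fill over integer indices.
label_connected <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(m)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      idx <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      nbr_r <- r + off_r
      nbr_c <- c + off_c
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nbr <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      nbr <- nbr[m[nbr] & lab[nbr] == 0L]
      if (length(nbr)) {
        lab[nbr] <- cur
        stack <- c(stack, nbr)
      }
    }
  }
  lab
}
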