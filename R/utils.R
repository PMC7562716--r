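#' @keywords internal
"_PACKAGE"

# The three lesion classes, in fixed order. Integer codes in label masks are
# background = 0L, then match(class, lesion_classes()).

#' Lesion class vocabulary
#'
#' The closed set of tissue classes used throughout the package, in the fixed
#' order (normal, gastritis, cancer). Label masks code background as 0 and a
#' class as its position in this vector.
#'
#' @return Character vector of length 3.
#' @export
lesion_classes <- function() c("normal", "gastritis", "cancer")

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "slideheat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a global seed
#'
#' Deterministically fans a single integer seed out to per-stage seeds by
#' hashing a label string, so that independent pipeline stages never share an
#' RNG stream. The result is always a valid 32-bit R integer.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Validate an image array: h x w x 3 numeric in [0, 255].
check_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("%s must be an h x w x 3 RGB array", arg)
  if (!is.numeric(img)) stopf("%s must be numeric", arg)
  invisible(img)
}

# Luminosity used for background detection and tissue thresholding.
luminosity <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

# Block-average an h x w (x 3) array by an integer factor; partial edge
# blocks average over the pixels that exist.
block_average <- function(arr, ds) {
  stopifnot(is_count(ds))
  if (ds == 1) return(arr)
  avg2d <- function(m) {
    h <- nrow(m); w <- ncol(m)
    gr <- (seq_len(h) - 1L) %/% ds
    gc <- (seq_len(w) - 1L) %/% ds
    s <- rowsum(t(rowsum(m, gr, reorder = TRUE)), gc, reorder = TRUE)
    cnt <- outer(tabulate(gc + 1L), tabulate(gr + 1L))
    t(s / cnt)
  }
  if (length(dim(arr)) == 2) return(avg2d(arr))
  out <- vapply(seq_len(dim(arr)[3]), function(k) avg2d(arr[, , k]),
                matrix(0, ceiling(dim(arr)[1] / ds), ceiling(dim(arr)[2] / ds)))
  out
}

# Area-interpolation resize of a matrix to nr x nc: each output pixel is the
# exact average of the input region it covers (box filter with fractional
# overlap weights), implemented as two dense weight-matrix products.
area_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * s
    hi <- i * s
    j0 <- floor(lo)
    j1 <- min(ceiling(hi), n_in)
    js <- seq.int(j0, j1 - 1)
    w <- pmin(hi, js + 1) - pmax(lo, js)
    W[i, js + 1] <- w / s
  }
  W
}

#' Resize a raster by area interpolation
#'
#' Downsizes (or upsizes) an image so each output pixel equals the exact
#' area-weighted average of the input pixels it covers. This is the box/area
#' filter commonly used for antialiased downscaling of histology patches.
#'
#' @param img Matrix or h x w x 3 array.
#' @param out_h,out_w Output dimensions in pixels; `out_w` defaults to `out_h`.
#' @return Resized matrix or array.
#' @export
resize_area <- function(img, out_h, out_w = out_h) {
  stopifnot(is_count(out_h), is_count(out_w))
  d <- dim(img)
  A <- area_weights(d[1], out_h)
  B <- area_weights(d[2], out_w)
  if (length(d) == 2) return(A %*% img %*% t(B))
  out <- array(0, c(out_h, out_w, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- A %*% img[, , k] %*% t(B)
  out
}
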