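# Slide rasters and polygon annotations.
#
# Coordinate convention used by every module: 0-based, half-open pixel
# coordinates with x = column and y = row, so a w x h region at origin
# (x0, y0) covers columns x0 .. x0+w-1 and rows y0 .. y0+h-1 at level 0.
# Pixel (x, y) has its center at (x + 0.5, y + 0.5).

#' Construct a slide image
#'
#' Wraps an 8-bit RGB raster (values 0--255) as a slide with a resolution
#' pyramid defined by power-of-two downsample factors. Level 0 is the full
#' raster; level L has downsample 2^L and is computed on demand by block
#' averaging, so plain PNG/TIFF rasters behave like pyramidal slides behind
#' one accessor contract.
#'
#' @param data h x w x 3 numeric array with values in 0--255 (level 0),
#'   or a matrix (replicated to three channels).
#' @param id Slide identifier string.
#' @param n_levels Number of pyramid levels exposed (downsamples 2^0..2^(n-1)).
#' @return An object of class `slideheat_slide`.
#' @export
slide_image <- function(data, id = "slide", n_levels = 4) {
  if (is.matrix(data)) data <- array(rep(data, 3), c(dim(data), 3))
  check_rgb(data, "slide data")
  if (min(data) < 0 || max(data) > 255) stopf("slide data must lie in [0, 255]")
  structure(
    list(data = data, width = dim(data)[2], height = dim(data)[1],
         downsamples = 2^(seq_len(n_levels) - 1), id = id),
    class = "slideheat_slide"
  )
}

#' @export
print.slideheat_slide <- function(x, ...) {
  cat(sprintf("<slide '%s'> %d x %d px, levels: %s\n", x$id, x$width, x$height,
              paste(x$downsamples, collapse = "/")))
  invisible(x)
}

#' Read a slide raster from PNG or TIFF
#'
#' @param path Path to an 8-bit RGB (or gray) PNG/TIFF file.
#' @param id Slide identifier; defaults to the file name.
#' @return A `slideheat_slide`.
#' @export
read_slide <- function(path, id = basename(path)) {
  if (!file.exists(path)) stopf("slide file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported slide format '%s' (PNG or TIFF expected)", ext)
  )
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3]
  slide_image(round(raw * 255), id = id)
}

#' Write a slide raster to PNG or TIFF
#'
#' @param slide A `slideheat_slide` or RGB array in 0--255.
#' @param path Output path (.png, .tif or .tiff).
#' @export
write_slide <- function(slide, path) {
  arr <- if (inherits(slide, "slideheat_slide")) slide$data else slide
  check_rgb(arr, "slide")
  ext <- tolower(tools::file_ext(path))
  img <- clamp(arr, 0, 255) / 255
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stopf("unsupported output format '%s'", ext)
  )
  invisible(path)
}

#' Read a rectangular region from a slide
#'
#' @param slide A `slideheat_slide`.
#' @param origin Level-0 (x, y) of the region's top-left corner (0-based).
#' @param size (w, h) of the region in pixels *at the requested level*.
#' @param level Pyramid level index (0-based).
#' @return A h x w x 3 array of 8-bit values.
#' @export
read_region <- function(slide, origin, size, level = 0) {
  stopifnot(inherits(slide, "slideheat_slide"))
  if (!(level %in% (seq_along(slide$downsamples) - 1)))
    stopf("level %d does not exist (levels 0..%d)", level, length(slide$downsamples) - 1)
  if (length(origin) != 2 || length(size) != 2 || any(size < 1))
    stopf("origin must be (x, y) and size a positive (w, h)")
  ds <- slide$downsamples[level + 1]
  x0 <- origin[1]; y0 <- origin[2]; w <- size[1]; h <- size[2]
  # a level-L raster has ceiling(dim / ds) pixels; the last one may be partial
  lw <- ceiling(slide$width / ds); lh <- ceiling(slide$height / ds)
  if (x0 < 0) stopf("region x origin %g is outside the slide (x >= 0 required)", x0)
  if (y0 < 0) stopf("region y origin %g is outside the slide (y >= 0 required)", y0)
  if (x0 / ds + w > lw)
    stopf("region right edge %g exceeds slide width %d at level %d", x0 + w * ds, slide$width, level)
  if (y0 / ds + h > lh)
    stopf("region bottom edge %g exceeds slide height %d at level %d", y0 + h * ds, slide$height, level)
  rows <- seq.int(y0 + 1, min(y0 + h * ds, slide$height))
  cols <- seq.int(x0 + 1, min(x0 + w * ds, slide$width))
  sub <- slide$data[rows, cols, , drop = FALSE]
  if (ds > 1) sub <- block_average(sub, ds)
  sub
}

#' Slide thumbnail at a given downsample
#'
#' Block-averages the level-0 raster by an arbitrary integer factor (not
#' restricted to the pyramid levels); used for tissue masking.
#'
#' @param slide A `slideheat_slide`.
#' @param downsample Integer downsample factor (>= 1).
#' @return RGB array of size ceiling(h/ds) x ceiling(w/ds) x 3.
#' @export
slide_thumbnail <- function(slide, downsample = 32) {
  stopifnot(inherits(slide, "slideheat_slide"), is_count(downsample))
  block_average(slide$data, downsample)
}

# ---- annotations ------------------------------------------------------------

#' Construct an annotation set
#'
#' @param labels Character vector of class labels (one per polygon), each in
#'   `lesion_classes()`.
#' @param polygons List of n x 2 matrices of level-0 (x, y) vertices; every
#'   polygon is closed implicitly and must have at least 3 vertices.
#' @param slide_id Slide identifier.
#' @return An object of class `slideheat_annotations`.
#' @export
annotation_set <- function(labels = character(), polygons = list(), slide_id = "slide") {
  if (length(labels) != length(polygons))
    stopf("labels and polygons must have equal length")
  bad <- setdiff(labels, lesion_classes())
  if (length(bad))
    stopf("unknown annotation label '%s'; accepted labels: %s",
          bad[1], paste(lesion_classes(), collapse = ", "))
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stopf("polygon %d must be an n x 2 vertex matrix with n >= 3", i)
  }
  structure(list(labels = labels, polygons = polygons, slide_id = slide_id),
            class = "slideheat_annotations")
}

#' @export
print.slideheat_annotations <- function(x, ...) {
  cat(sprintf("<annotations for '%s'> %d polygon(s): %s\n", x$slide_id,
              length(x$labels), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Write annotations as ASAP-style XML
#'
#' Dialect: `ASAP_Annotations/Annotations/Annotation` elements with attributes
#' `Name`, `Type="Polygon"` and `PartOfGroup` (the class label), each holding
#' `Coordinates/Coordinate` elements with attributes `Order`, `X`, `Y`.
#'
#' @param annotations A `slideheat_annotations`.
#' @param path Output XML path.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "slideheat_annotations"))
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_along(annotations$labels)) {
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("Annotation %d", i - 1),
                             Type = "Polygon",
                             PartOfGroup = annotations$labels[i])
    cs <- xml2::xml_add_child(a, "Coordinates")
    p <- annotations$polygons[[i]]
    for (j in seq_len(nrow(p))) {
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(j - 1),
                          X = format(p[j, 1], digits = 15),
                          Y = format(p[j, 2], digits = 15))
    }
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in unique(annotations$labels))
    xml2::xml_add_child(groups, "Group", Name = g, PartOfGroup = "None")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Parse an ASAP-style annotation XML file
#'
#' @param path XML file path.
#' @param slide_id Slide identifier to attach; defaults to the file name.
#' @return A `slideheat_annotations`. Unknown `PartOfGroup` labels and
#'   polygons with fewer than 3 vertices are rejected with an error.
#' @export
parse_annotations <- function(path, slide_id = basename(path)) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  doc <- xml2::read_xml(path)  # malformed XML -> xml2 parse error with line info
  nodes <- xml2::xml_find_all(doc, ".//Annotation")
  labels <- character(0)
  polygons <- list()
  for (a in nodes) {
    lab <- xml2::xml_attr(a, "PartOfGroup")
    if (!(lab %in% lesion_classes()))
      stopf("unknown annotation label '%s'; accepted labels: %s",
            lab, paste(lesion_classes(), collapse = ", "))
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    ord <- as.integer(xml2::xml_attr(coords, "Order"))
    p <- cbind(as.numeric(xml2::xml_attr(coords, "X")),
               as.numeric(xml2::xml_attr(coords, "Y")))[order(ord), , drop = FALSE]
    if (nrow(p) < 3)
      stopf("annotation '%s' has %d vertices; polygons need at least 3",
            xml2::xml_attr(a, "Name"), nrow(p))
    labels <- c(labels, lab)
    polygons <- c(polygons, list(p))
  }
  annotation_set(labels, polygons, slide_id)
}

# Even-odd scanline fill of one polygon at pixel centers.
# Returns a logical nr x nc matrix; pixel (row r, col c) has center
# ((c - 0.5) * ds, (r - 0.5) * ds) in level-0 coordinates.
polygon_fill <- function(poly, nr, nc, ds) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  out <- matrix(FALSE, nr, nc)
  xc <- (seq_len(nc) - 0.5) * ds
  r0 <- max(1L, floor(min(ys) / ds - 0.5) + 1L)
  r1 <- min(nr, ceiling(max(ys) / ds + 0.5))
  if (r0 > r1) return(out)
  for (r in r0:r1) {
    yc <- (r - 0.5) * ds
    hit <- (ys <= yc & y2 > yc) | (y2 <= yc & ys > yc)
    if (!any(hit)) next
    cx <- xs[hit] + (yc - ys[hit]) * (x2[hit] - xs[hit]) / (y2[hit] - ys[hit])
    out[r, ] <- findInterval(xc, sort(cx)) %% 2L == 1L
  }
  out
}

#' Rasterize annotations to a class-coded label mask
#'
#' A pixel belongs to a polygon iff its center is inside under the even-odd
#' rule; polygons later in the set overwrite earlier ones; pixels inside no
#' polygon get the background code 0.
#'
#' @param annotations A `slideheat_annotations`.
#' @param canvas_size Level-0 (width, height) of the slide in pixels.
#' @param downsample Integer downsample factor (>= 1) of the output mask.
#' @return Integer matrix of size ceiling(h/ds) x ceiling(w/ds); codes are 0
#'   (background) or match(label, lesion_classes()).
#' @export
rasterize_annotations <- function(annotations, canvas_size, downsample = 1) {
  stopifnot(inherits(annotations, "slideheat_annotations"))
  if (!is_count(downsample)) stopf("downsample must be a positive integer")
  nc <- ceiling(canvas_size[1] / downsample)
  nr <- ceiling(canvas_size[2] / downsample)
  mask <- matrix(0L, nr, nc)
  for (i in seq_along(annotations$labels)) {
    code <- match(annotations$labels[i], lesion_classes())
    inside <- polygon_fill(annotations$polygons[[i]], nr, nc, downsample)
    mask[inside] <- code
  }
  mask
}
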