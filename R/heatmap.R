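# Malignancy-probability heatmap assembly and IO.
#
# The heatmap value at a point is the maximum malignancy probability over all
# patches containing that point: H(x, y) = max_{p : (x,y) in p} Pr(p != normal).
# A finite raster needs a cell convention: each cell takes the value at its
# center, with patch footprints treated as half-open rectangles.

#' Assemble a malignancy heatmap from patch predictions
#'
#' @param predictions Data frame with columns `x`, `y`, `w`, `h` (level-0
#'   half-open footprint rectangles) and `prob` (malignancy probability).
#' @param canvas_size Level-0 (width, height) of the slide.
#' @param cell_size Level-0 pixels per heatmap cell (default 1024, the
#'   non-overlapping heatmap patch size).
#' @param tissue A `slideheat_tissue_mask` or logical matrix to resample onto
#'   the heatmap grid (a cell is tissue if any of its mask pixels are), or
#'   NULL.
#' @param slide_id Identifier stored with the heatmap.
#' @return An object of class `slideheat_heatmap`: list with `values`
#'   (ny x nx matrix in [0,1], `NA` = no covering patch), `cell_size`,
#'   `tissue` (logical matrix or NULL), `slide_id`.
#' @export
assemble_heatmap <- function(predictions, canvas_size, cell_size = 1024,
                             tissue = NULL, slide_id = "slide") {
  nx <- ceiling(canvas_size[1] / cell_size)
  ny <- ceiling(canvas_size[2] / cell_size)
  H <- matrix(NA_real_, ny, nx)
  if (is.null(predictions) || nrow(predictions) == 0) {
    warning("empty prediction list: heatmap is all no-data", call. = FALSE)
  } else {
    stopifnot(all(c("x", "y", "w", "h", "prob") %in% names(predictions)))
    if (any(predictions$prob < 0 | predictions$prob > 1))
      stopf("probabilities must lie in [0, 1]")
    if (any(predictions$x < 0 | predictions$y < 0 |
            predictions$x + predictions$w > nx * cell_size |
            predictions$y + predictions$h > ny * cell_size))
      stopf("patch footprint outside the canvas")
    for (i in seq_len(nrow(predictions))) {
      p <- predictions[i, ]
      # cells whose center (j + 0.5) * cell falls in [x, x + w)
      cx0 <- max(0L, ceiling(p$x / cell_size - 0.5))
      cx1 <- min(nx - 1L, ceiling((p$x + p$w) / cell_size - 0.5) - 1L)
      cy0 <- max(0L, ceiling(p$y / cell_size - 0.5))
      cy1 <- min(ny - 1L, ceiling((p$y + p$h) / cell_size - 0.5) - 1L)
      if (cx1 < cx0 || cy1 < cy0) next
      rows <- (cy0:cy1) + 1L; cols <- (cx0:cx1) + 1L
      H[rows, cols] <- pmax(H[rows, cols], p$prob, na.rm = TRUE)
    }
  }
  tis <- NULL
  if (!is.null(tissue)) {
    m <- if (inherits(tissue, "slideheat_tissue_mask")) tissue$mask else tissue
    ds <- if (inherits(tissue, "slideheat_tissue_mask")) tissue$downsample else 1
    ratio <- cell_size / ds
    tis <- matrix(FALSE, ny, nx)
    for (r in seq_len(ny)) for (c in seq_len(nx)) {
      rr <- (floor((r - 1) * ratio) + 1):min(ceiling(r * ratio), nrow(m))
      cc <- (floor((c - 1) * ratio) + 1):min(ceiling(c * ratio), ncol(m))
      tis[r, c] <- any(m[rr, cc])
    }
  }
  structure(list(values = H, cell_size = cell_size, tissue = tis,
                 slide_id = slide_id),
            class = "slideheat_heatmap")
}

#' @export
print.slideheat_heatmap <- function(x, ...) {
  cat(sprintf("<heatmap '%s'> %d x %d cells of %d px, %d no-data\n",
              x$slide_id, nrow(x$values), ncol(x$values), x$cell_size,
              sum(is.na(x$values))))
  invisible(x)
}

#' Plot a heatmap in false color
#'
#' @param x A `slideheat_heatmap`.
#' @param ... Passed to `image`.
#' @export
plot.slideheat_heatmap <- function(x, ...) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "Inferno"), axes = FALSE,
                  main = sprintf("malignancy heatmap: %s", x$slide_id), ...)
  invisible(x)
}

#' Write / read a heatmap
#'
#' The probability raster is written as a single-channel 16-bit TIFF
#' (probability scaled to 0..65535, no-data stored as 0 and recorded in the
#' JSON sidecar), next to a `.json` sidecar holding the cell size, slide id,
#' no-data cells and tissue grid.
#'
#' @param heatmap A `slideheat_heatmap`.
#' @param path Output `.tif` path; the sidecar gets the same stem + `.json`.
#' @export
write_heatmap <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "slideheat_heatmap"))
  v <- heatmap$values
  raw <- ifelse(is.na(v), 0, v)
  tiff::writeTIFF(raw, path, bits.per.sample = 16L)
  sidecar <- list(slide_id = heatmap$slide_id, cell_size = heatmap$cell_size,
                  nrow = nrow(v), ncol = ncol(v),
                  nodata_cells = which(is.na(v)) - 1L,
                  tissue = if (!is.null(heatmap$tissue)) which(heatmap$tissue) - 1L)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  raw <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  v <- matrix(raw, meta$nrow, meta$ncol)
  if (length(meta$nodata_cells)) v[meta$nodata_cells + 1L] <- NA_real_
  tis <- NULL
  if (!is.null(meta$tissue)) {
    tis <- matrix(FALSE, meta$nrow, meta$ncol)
    tis[meta$tissue + 1L] <- TRUE
  }
  structure(list(values = v, cell_size = meta$cell_size, tissue = tis,
                 slide_id = meta$slide_id),
            class = "slideheat_heatmap")
}
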