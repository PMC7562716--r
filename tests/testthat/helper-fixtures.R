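# Small fixtures shared across test files, built in code.

# A square polygon as an n x 2 vertex matrix.
square_poly <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# A small two-lesion synthetic slide (normal left, cancer right).
demo_slide <- function(seed = 3, side = 256) {
  m <- round(side * 0.06)
  half <- round(side / 2)
  polys <- list(
    list(class = "normal", vertices = square_poly(m, m, half - 2 * m)),
    list(class = "cancer",
         vertices = cbind(c(half + m, side - m, side - m, half + m),
                          c(m, m, side - m, side - m)))
  )
  generate_synthetic_slide(slide_spec(side, side, polys, seed = seed))
}

# A random heatmap with a plausible mix of background, mid and high
# probabilities, plus a small no-data border.
random_heatmap <- function(seed, nr = 24, nc = 24) {
  set.seed(seed)
  v <- matrix(stats::runif(nr * nc), nr, nc)
  hot <- matrix(stats::runif(nr * nc) < 0.3, nr, nc)
  v[hot] <- stats::runif(sum(hot), 0.85, 1)
  v[1, 1] <- NA  # a no-data cell
  tissue <- matrix(stats::runif(nr * nc) < 0.9, nr, nc)
  structure(list(values = v, cell_size = 1024, tissue = tissue,
                 slide_id = sprintf("rand%d", seed)),
            class = "slideheat_heatmap")
}

# Heatmap wrapper around an explicit values matrix.
heatmap_from_matrix <- function(v, tissue = NULL, cell_size = 1024) {
  structure(list(values = v, cell_size = cell_size, tissue = tissue,
                 slide_id = "fixture"),
            class = "slideheat_heatmap")
}

# Tissue-mask wrapper around a logical matrix.
mask_from_matrix <- function(m, downsample = 1) {
  structure(list(mask = m, downsample = downsample, threshold = NA,
                 close_radius = 0, min_area_fraction = 0),
            class = "slideheat_tissue_mask")
}

accuracy_of <- function(classifier, patch_set) {
  probs <- predict(classifier, patch_set)
  mean(lesion_classes()[max.col(probs)] == as.character(patch_set$labels))
}
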