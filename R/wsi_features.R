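# Heatmap morphometry: tumor regions, the 44-feature vector, and
# random-forest slide classification.

#' Names of the 44 heatmap features, in canonical order
#'
#' Indices 1-26 are region morphometry (regions of cells at or above a
#' probability threshold: counts, areas, perimeters, eccentricities,
#' extents); 27-36 are statistics of the per-cell probabilities over tissue;
#' 37-44 are the proportions of tissue cells in fixed high-probability bins.
#'
#' @return Character vector of length 44.
#' @export
feature_names_44 <- function() {
  c("n_tumor_regions_large",                                     # 1
    "tumor_area_fraction",                                       # 2
    "largest_region_area_p50", "largest_region_major_axis_p50",  # 3-4
    "high_prob_cell_fraction", "tumor_region_mean_prob",         # 5-6
    paste0("area_", c("max", "mean", "var", "skew", "kurt")),    # 7-11
    paste0("perim_", c("max", "mean", "var", "skew", "kurt")),   # 12-16
    paste0("ecc_", c("max", "mean", "var", "skew", "kurt")),     # 17-21
    paste0("extent_", c("max", "mean", "var", "skew", "kurt")),  # 22-26
    "prob_mean", "prob_var", "prob_sd", "prob_median",           # 27-30
    "prob_mode", "prob_min", "prob_max", "prob_range",           # 31-34
    "prob_sum",                                                  # 35
    "malignant_prob_avg",                                        # 36
    "bin_gt_0.999", "bin_0.99_0.999", "bin_0.95_0.99",           # 37-39
    "bin_0.9_0.95", "bin_0.8_0.9", "bin_0.7_0.8",                # 40-42
    "bin_0.6_0.7", "bin_0.5_0.6")                                # 43-44
}

# Region properties of one labeled component given its cell coordinates
# (1-based rows/cols) on the heatmap lattice. Area in cells; perimeter as the
# count of cell edges adjacent to non-region cells or the canvas border;
# eccentricity and major axis from the equivalent ellipse of the second
# central moments; extent = area / bounding-box area.
region_properties <- function(rows, cols, values_at_cells, region_id,
                              member_lookup, nr, nc) {
  area <- length(rows)
  # perimeter: for each cell, 4 minus its 4-neighbors inside the region
  per <- 0L
  for (i in seq_len(area)) {
    r <- rows[i]; c <- cols[i]
    for (d in 1:4) {
      rr <- r + c(-1L, 1L, 0L, 0L)[d]
      cc <- c + c(0L, 0L, -1L, 1L)[d]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc ||
          member_lookup[(cc - 1L) * nr + rr] != region_id) per <- per + 1L
    }
  }
  mr <- mean(rows); mc <- mean(cols)
  mu20 <- mean((cols - mc)^2)
  mu02 <- mean((rows - mr)^2)
  mu11 <- mean((cols - mc) * (rows - mr))
  tr <- (mu20 + mu02) / 2
  dt <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr + dt; l2 <- max(tr - dt, 0)
  major <- 4 * sqrt(l1)
  ecc <- if (l1 <= 0) 0 else sqrt(1 - l2 / l1)
  bbox <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  c(area = area, perimeter = per, eccentricity = ecc,
    extent = area / bbox, major_axis = major,
    mean_prob = mean(values_at_cells))
}

#' Tumor regions of a heatmap at a probability threshold
#'
#' Binarizes the heatmap at `value >= p_threshold` over tissue cells, labels
#' 8-connected components, and computes per-region morphometry.
#'
#' @param heatmap A `slideheat_heatmap`.
#' @param p_threshold Tumor-probability threshold.
#' @return An object of class `slideheat_region_set`: data frame with columns
#'   `label`, `area`, `perimeter`, `eccentricity`, `extent`, `major_axis`,
#'   `mean_prob`, carrying attributes `p_threshold` and `labels` (the label
#'   matrix).
#' @export
threshold_regions <- function(heatmap, p_threshold) {
  stopifnot(inherits(heatmap, "slideheat_heatmap"))
  v <- heatmap$values
  tissue <- heatmap_tissue_cells(heatmap)
  bin <- !is.na(v) & tissue & v >= p_threshold
  lab <- label_connected(bin)
  n <- max(lab)
  nr <- nrow(v); nc <- ncol(v)
  props <- matrix(0, n, 6,
                  dimnames = list(NULL, c("area", "perimeter", "eccentricity",
                                          "extent", "major_axis", "mean_prob")))
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    props[k, ] <- region_properties(rows, cols, v[idx], k, lab, nr, nc)
  }
  out <- data.frame(label = seq_len(n), props)
  attr(out, "p_threshold") <- p_threshold
  attr(out, "labels") <- lab
  class(out) <- c("slideheat_region_set", "data.frame")
  out
}

# Tissue cells of a heatmap: flagged tissue when a companion grid exists,
# otherwise every cell covered by at least one patch.
heatmap_tissue_cells <- function(heatmap) {
  if (!is.null(heatmap$tissue)) heatmap$tissue & !is.na(heatmap$values)
  else !is.na(heatmap$values)
}

# max / mean / population variance / skewness / Pearson (non-excess)
# kurtosis, with the empty-set (and zero-variance) convention: all 0.
dist_stats <- function(x) {
  if (!length(x)) return(c(max = 0, mean = 0, var = 0, skew = 0, kurt = 0))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(c(max = max(x), mean = m, var = 0, skew = 0, kurt = 0))
  c(max = max(x), mean = m, var = m2,
    skew = mean((x - m)^3) / m2^1.5, kurt = mean((x - m)^4) / m2^2)
}

#' Extract the 44-feature morphometric vector from a heatmap
#'
#' Features 1-26 come from tumor region sets thresholded at 0.90 (regions,
#' areas, perimeters, eccentricities) and 0.50 (largest-region area/axis,
#' extents); 27-35 are mean, variance, standard deviation, median, mode,
#' min, max, range and sum of all tissue-cell probabilities (mode = midpoint
#' of the fullest bin of a 100-bin histogram on [0, 1]); 36 is the average
#' malignant probability; 37-44 the proportions of tissue cells in the bins
#' (0.999, 1], (0.99, 0.999], (0.95, 0.99], (0.9, 0.95], (0.8, 0.9],
#' (0.7, 0.8], (0.6, 0.7], (0.5, 0.6]. Statistics of an empty region set
#' are 0. Cells without a covering patch are excluded from the tissue set.
#'
#' @param heatmap A `slideheat_heatmap` with at least one tissue cell.
#' @return Named numeric vector of length 44 (class `slideheat_features44`).
#' @export
extract_feature_vector <- function(heatmap) {
  stopifnot(inherits(heatmap, "slideheat_heatmap"))
  tissue <- heatmap_tissue_cells(heatmap)
  n_tissue <- sum(tissue)
  if (n_tissue == 0) stopf("heatmap has no tissue cells with predictions")
  p <- heatmap$values[tissue]
  r90 <- threshold_regions(heatmap, 0.90)
  r50 <- threshold_regions(heatmap, 0.50)
  f <- numeric(44)
  f[1] <- sum(r90$area >= 0.05 * n_tissue)
  f[2] <- sum(r90$area) / n_tissue
  if (nrow(r50)) {
    big <- which.max(r50$area)
    f[3] <- r50$area[big]
    f[4] <- r50$major_axis[big]
  }
  f[5] <- sum(p >= 0.90) / n_tissue
  f[6] <- if (any(p >= 0.90)) mean(p[p >= 0.90]) else 0
  f[7:11] <- dist_stats(r90$area)
  f[12:16] <- dist_stats(r90$perimeter)
  f[17:21] <- dist_stats(r90$eccentricity)
  f[22:26] <- dist_stats(r50$extent)
  m <- mean(p)
  v <- mean((p - m)^2)
  f[27] <- m
  f[28] <- v
  f[29] <- sqrt(v)
  f[30] <- stats::median(p)
  # mode over right-closed percent bins, reported as the fullest bin's lower
  # edge so a malignancy-free heatmap reports mode 0
  counts <- tabulate(pmax(ceiling(p * 100), 1L), nbins = 100L)
  f[31] <- (which.max(counts) - 1L) / 100
  f[32] <- min(p)
  f[33] <- max(p)
  f[34] <- max(p) - min(p)
  f[35] <- sum(p)
  f[36] <- m
  edges_hi <- c(1, 0.999, 0.99, 0.95, 0.9, 0.8, 0.7, 0.6)
  edges_lo <- c(0.999, 0.99, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5)
  f[37] <- sum(p > 0.999) / n_tissue
  for (b in 2:8) f[36 + b] <- sum(p > edges_lo[b] & p <= edges_hi[b]) / n_tissue
  names(f) <- feature_names_44()
  structure(f, class = "slideheat_features44")
}

#' @export
print.slideheat_features44 <- function(x, ...) {
  cat("<44-feature heatmap vector>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Write feature vectors as CSV
#'
#' @param features Matrix/data frame with 44 named columns (one row per
#'   slide), or a list of `slideheat_features44`.
#' @param slide_ids Row identifiers.
#' @param labels Optional slide labels appended as a `label` column.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(features, slide_ids, path, labels = NULL) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, unclass))
  df <- data.frame(slide = slide_ids, features, check.names = FALSE)
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Train the slide-level random-forest classifier
#'
#' Fits a random forest on 44-feature vectors (500 trees, sqrt(44) features
#' per split by default) and reports out-of-bag accuracy and the confusion
#' matrix. Deterministic under `seed`.
#'
#' @param features n x 44 matrix or data frame of feature vectors.
#' @param labels Slide labels (factor; e.g. benign/cancer or the three lesion
#'   classes).
#' @param config List: `ntree` (default 500), `mtry` (default floor(sqrt(44))).
#' @param seed Integer seed.
#' @return An object of class `slideheat_slide_classifier`.
#' @export
train_slide_classifier <- function(features, labels, config = list(), seed = 1) {
  cfg <- utils::modifyList(list(ntree = 500, mtry = floor(sqrt(44))), config)
  features <- as.matrix(features)
  if (ncol(features) != 44)
    stopf("feature schema mismatch: expected 44 features, got %d", ncol(features))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("slide training requires at least two classes")
  if (nrow(features) < 10) stopf("at least 10 slides are required")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(features, labels, ntree = cfg$ntree,
                                   mtry = cfg$mtry)
  structure(list(model = rf, classes = levels(labels),
                 oob_accuracy = 1 - rf$err.rate[cfg$ntree, "OOB"],
                 confusion = rf$confusion, config = cfg, seed = seed),
            class = "slideheat_slide_classifier")
}

#' @export
print.slideheat_slide_classifier <- function(x, ...) {
  cat(sprintf("<slide classifier> %d trees, classes %s, OOB accuracy %.3f\n",
              x$config$ntree, paste(x$classes, collapse = "/"), x$oob_accuracy))
  invisible(x)
}

#' Classify a slide from its 44-feature vector
#'
#' @param model A `slideheat_slide_classifier`.
#' @param features A 44-feature vector (or n x 44 matrix).
#' @return List with `label` (majority-vote class) and `probabilities`
#'   (per-class vote fractions summing to 1).
#' @export
classify_slide <- function(model, features) {
  stopifnot(inherits(model, "slideheat_slide_classifier"))
  if (inherits(features, "slideheat_features44")) features <- unclass(features)
  if (is.null(dim(features))) features <- matrix(features, 1,
                                                 dimnames = list(NULL, names(features)))
  if (ncol(features) != 44)
    stopf("feature schema mismatch: expected 44 features, got %d", ncol(features))
  votes <- stats::predict(model$model, features, type = "vote", norm.votes = TRUE)
  lab <- model$classes[max.col(votes, ties.method = "first")]
  list(label = lab, probabilities = votes)
}

#' Split slide ids into train / test / validation sets
#'
#' Sizes are round(n x f_train) and round(n x f_val), with the remainder as
#' the test set; the three lists are disjoint and their union is the input.
#'
#' @param ids Vector of slide identifiers.
#' @param fractions (train, test, validation) fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `test`, `validation`.
#' @export
split_cohort <- function(ids, fractions = c(0.7, 0.2, 0.1), seed = 1) {
  n <- length(ids)
  if (n < 3) stopf("at least 3 ids are required to split")
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n_train <- round(n * fractions[1])
  n_val <- round(n * fractions[3])
  n_test <- n - n_train - n_val
  if (n_test < 0) stopf("fractions leave no room for a test set")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  list(train = perm[seq_len(n_train)],
       test = perm[n_train + seq_len(n_test)],
       validation = perm[n_train + n_test + seq_len(n_val)])
}
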