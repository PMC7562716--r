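test_that("region properties match closed forms on simple shapes", {
  v <- matrix(0.95, 12, 12)
  hm <- heatmap_from_matrix(v)
  rs <- threshold_regions(hm, 0.9)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$area, 144)
  expect_equal(rs$extent, 1.0)
  expect_equal(rs$eccentricity, 0)
  expect_equal(rs$perimeter, 4 * 12)

  # 10 x 10 square inside a larger canvas
  v2 <- matrix(0.1, 20, 20)
  v2[5:14, 3:12] <- 0.95
  rs2 <- threshold_regions(heatmap_from_matrix(v2), 0.9)
  expect_equal(rs2$area, 100)
  expect_equal(rs2$extent, 1.0)
  expect_equal(rs2$eccentricity, 0)
})

test_that("region properties equal the brute-force oracle on random blobs", {
  for (s in 1:5) {
    set.seed(s)
    v <- matrix(runif(18 * 18), 18, 18)
    hm <- heatmap_from_matrix(v)
    rs <- threshold_regions(hm, 0.6)
    lab <- attr(rs, "labels")
    olab <- oracle_label_8(!is.na(v) & v >= 0.6)
    # same partition (label ids may differ): compare region multisets
    expect_equal(max(lab), max(olab))
    for (k in seq_len(max(lab))) {
      cells <- which(lab == k)
      ok <- unique(olab[cells])
      expect_length(ok, 1)
      o <- oracle_region_props(olab, v, ok)
      expect_equal(rs$area[k], o$area)
      expect_equal(rs$perimeter[k], o$perimeter)
      expect_equal(rs$eccentricity[k], o$eccentricity, tolerance = 1e-12)
      expect_equal(rs$extent[k], o$extent, tolerance = 1e-12)
      expect_equal(rs$major_axis[k], o$major_axis, tolerance = 1e-12)
      expect_equal(rs$mean_prob[k], o$mean_prob, tolerance = 1e-12)
    }
  }
})

test_that("feature extraction has the empty-tumor and constant-field closed forms", {
  f0 <- extract_feature_vector(heatmap_from_matrix(matrix(0, 10, 10)))
  expect_length(unclass(f0), 44)
  expect_true(all(f0[1:26] == 0))
  expect_true(all(f0[c(27:29, 31:35)] == 0))
  expect_true(all(f0[37:44] == 0))

  fu <- extract_feature_vector(heatmap_from_matrix(matrix(0.95, 10, 10)))
  expect_equal(unname(fu["tumor_area_fraction"]), 1.0)
  expect_equal(unname(fu["high_prob_cell_fraction"]), 1.0)
  expect_equal(unname(fu["malignant_prob_avg"]), 0.95)
  expect_equal(unname(fu["bin_gt_0.999"]), 0)
  expect_equal(unname(fu["bin_0.9_0.95"]), 1.0)
  expect_equal(unname(fu["prob_sum"]), 95)
  expect_error(extract_feature_vector(
    heatmap_from_matrix(matrix(NA_real_, 4, 4))), "no tissue")
})

test_that("the hand-built two-region heatmap matches the independent oracle", {
  v <- matrix(0.1, 50, 50)
  v[10:21, 5:16] <- 0.92   # region A: 12 x 12
  v[30:34, 40:44] <- 0.96  # region B: 5 x 5
  hm <- heatmap_from_matrix(v)
  f <- unclass(extract_feature_vector(hm))
  o <- oracle_features44(v, matrix(TRUE, 50, 50))
  expect_equal(unname(f), o, tolerance = 1e-10)
  expect_equal(unname(f["n_tumor_regions_large"]), 1)  # only A (144) >= 5% of 2500
  expect_equal(unname(f["area_max"]), 144)
  expect_equal(unname(f["largest_region_area_p50"]), 144)
})

test_that("feature extraction equals the oracle on 50 random heatmaps", {
  for (s in 1:50) {
    hm <- random_heatmap(s)
    f <- unclass(extract_feature_vector(hm))
    o <- oracle_features44(hm$values, hm$tissue)
    expect_equal(unname(f), o, tolerance = 1e-10)
  }
})

test_that("proportion features are scale-covariant, length/area features scale", {
  set.seed(23)
  v <- matrix(runif(16 * 16), 16, 16)
  v[4:9, 4:11] <- runif(48, 0.9, 1)
  f1 <- unclass(extract_feature_vector(heatmap_from_matrix(v)))
  v2 <- v[rep(1:16, each = 2), rep(1:16, each = 2)]  # double the resolution
  f2 <- unclass(extract_feature_vector(heatmap_from_matrix(v2)))
  prop_idx <- c(2, 5, 6, 27:34, 36:44)
  expect_equal(f2[prop_idx], f1[prop_idx], tolerance = 0.02)
  expect_equal(unname(f2["largest_region_area_p50"]),
               4 * unname(f1["largest_region_area_p50"]))
  expect_equal(unname(f2["area_max"]), 4 * unname(f1["area_max"]))
})

test_that("probability bins sum to the above-0.5 fraction", {
  for (s in 1:5) {
    hm <- random_heatmap(s + 60)
    f <- extract_feature_vector(hm)
    p <- hm$values[hm$tissue & !is.na(hm$values)]
    expect_equal(unname(sum(f[37:44])), mean(p > 0.5), tolerance = 1e-12)
    expect_lte(sum(f[37:44]), 1)
  }
})

test_that("split_cohort reproduces the 70/20/10 partition sizes", {
  sp <- split_cohort(seq_len(763), c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(lengths(sp), c(train = 534, test = 153, validation = 76))
  sp10 <- split_cohort(seq_len(10), c(0.7, 0.2, 0.1), seed = 2)
  expect_equal(lengths(sp10), c(train = 7, test = 2, validation = 1))
  expect_setequal(unlist(sp10), seq_len(10))
  expect_length(intersect(sp10$train, sp10$test), 0)
  expect_length(intersect(sp10$train, sp10$validation), 0)
  expect_error(split_cohort(1:2), "at least 3")
  expect_error(split_cohort(1:10, c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("slide classification by vote agrees with a manual tree count", {
  set.seed(31)
  X <- matrix(runif(40 * 44), 40)
  colnames(X) <- feature_names_44()
  y <- factor(rep(c("benign", "cancer"), each = 20))
  X[y == "cancer", 2] <- X[y == "cancer", 2] + 2
  m <- train_slide_classifier(X, y, config = list(ntree = 3), seed = 5)
  res <- classify_slide(m, X[1, ])
  expect_equal(sum(res$probabilities), 1)
  # manual vote count over the 3 trees
  votes <- stats::predict(m$model, X[1, , drop = FALSE], predict.all = TRUE)
  manual <- table(factor(votes$individual, levels = levels(y))) / 3
  expect_equal(as.vector(res$probabilities), as.vector(manual))
  expect_equal(res$label, names(which.max(manual)))

  expect_error(classify_slide(m, runif(10)), "schema")
  expect_error(train_slide_classifier(X[c(1:4, 21:24), ], y[c(1:4, 21:24)]),
               "at least 10")
  expect_error(train_slide_classifier(X, factor(rep("benign", 40))), "two classes")
})

test_that("same-seed slide-classifier training is reproducible", {
  set.seed(7)
  X <- matrix(runif(30 * 44), 30)
  colnames(X) <- feature_names_44()
  y <- factor(rep(c("benign", "cancer"), 15))
  m1 <- train_slide_classifier(X, y, config = list(ntree = 50), seed = 3)
  m2 <- train_slide_classifier(X, y, config = list(ntree = 50), seed = 3)
  expect_equal(classify_slide(m1, X)$label, classify_slide(m2, X)$label)
  expect_equal(m1$oob_accuracy, m2$oob_accuracy)
})

test_that("the full pipeline separates benign from cancerous slides", {
  clf <- train_patch_classifier(generate_patch_set(40, patch_size = 64, seed = 42),
                                seed = 1)
  featurize <- function(cl, seed) {
    poly <- square_poly(12, 12, 232)
    gen <- generate_synthetic_slide(
      slide_spec(256, 256, list(list(class = cl, vertices = poly)), seed = seed))
    mask <- compute_tissue_mask(slide_thumbnail(gen$slide, 8), 8, close_radius = 2)
    pt <- extract_patches(gen$slide, mask, scales = 64, out_side = 64,
                          min_tissue_fraction = 0.3)
    probs <- predict(clf, lapply(pt, `[[`, "raster"))
    preds <- data.frame(x = vapply(pt, `[[`, 0, "x"),
                        y = vapply(pt, `[[`, 0, "y"), w = 64, h = 64,
                        prob = malignancy_probability(probs))
    hm <- assemble_heatmap(preds, c(256, 256), cell_size = 64, tissue = mask)
    unclass(extract_feature_vector(hm))
  }
  n <- 15
  feats <- NULL; labs <- character(0)
  for (i in seq_len(n)) {
    feats <- rbind(feats, featurize(c("normal", "gastritis")[i %% 2 + 1], i))
    labs <- c(labs, "benign")
    feats <- rbind(feats, featurize("cancer", 1000 + i))
    labs <- c(labs, "cancer")
  }
  set.seed(9)
  idx <- sample(nrow(feats), 20)
  rf <- train_slide_classifier(feats[idx, ], labs[idx], seed = 1)
  pred <- classify_slide(rf, feats[-idx, ])
  expect_gte(mean(pred$label == labs[-idx]), 0.9)

  # label permutation drops accuracy to the chance band
  set.seed(10)
  rf0 <- train_slide_classifier(feats[idx, ], sample(labs[idx]), seed = 1)
  pred0 <- classify_slide(rf0, feats[-idx, ])
  expect_lte(mean(pred0$label == labs[-idx]), 0.8)
})
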