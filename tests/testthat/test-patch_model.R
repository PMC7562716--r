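test_that("the reference classifier separates synthetic classes held out", {
  tr <- generate_patch_set(60, patch_size = 64, seed = 101)
  te <- generate_patch_set(40, patch_size = 64, seed = 202)
  clf <- train_patch_classifier(tr, seed = 1)
  expect_gte(accuracy_of(clf, te), 0.85)

  # determinism: identical training run gives identical predictions
  clf2 <- train_patch_classifier(tr, seed = 1)
  expect_equal(predict(clf, te), predict(clf2, te))

  # probability triples are normalized
  probs <- predict(clf, te)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_equal(malignancy_probability(probs), 1 - probs[, "normal"])
})

test_that("permuted labels drop held-out accuracy to the chance band", {
  # enough patches per class that argmax amplification of label-noise
  # coincidences stays inside the three-class chance band
  tr <- generate_patch_set(100, patch_size = 48, seed = 11)
  set.seed(99)
  tr$labels <- sample(tr$labels)
  te <- generate_patch_set(100, patch_size = 48, seed = 12)
  clf <- train_patch_classifier(tr, seed = 1)
  acc <- accuracy_of(clf, te)
  expect_gte(acc, 0.20)
  expect_lte(acc, 0.47)
})

test_that("single-class training is refused", {
  ps <- generate_patch_set(4, patch_size = 32, classes = "normal", seed = 1)
  expect_error(train_patch_classifier(ps), "two classes")
})

test_that("evaluation metrics match hand arithmetic on built confusions", {
  # perfect predictor
  labels <- factor(rep(lesion_classes(), each = 4), levels = lesion_classes())
  perfect <- diag(3)[as.integer(labels), ]
  colnames(perfect) <- lesion_classes()
  ev <- evaluate_patch_classifier(perfect, labels = labels)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(diag(ev$confusion)), c(4, 4, 4))
  expect_equal(unname(ev$sensitivity), c(1, 1, 1))

  # all-cancer predictor on a balanced set: binary sens 1, spec 0
  allc <- matrix(rep(c(0, 0, 1), length(labels)), ncol = 3, byrow = TRUE,
                 dimnames = list(NULL, lesion_classes()))
  ev2 <- evaluate_patch_classifier(allc, labels = labels,
                                   binary_malignant = "cancer")
  expect_equal(unname(ev2$sensitivity["cancer"]), 1)
  expect_equal(unname(ev2$specificity["cancer"]), 0)
  expect_equal(ev2$binary$sensitivity, 1)
  expect_equal(ev2$binary$specificity, 0)

  # hand-built probabilistic confusion: metrics equal direct counts
  set.seed(13)
  probs <- matrix(runif(60 * 3), 60)
  probs <- probs / rowSums(probs)
  colnames(probs) <- lesion_classes()
  labs <- factor(sample(lesion_classes(), 60, TRUE), levels = lesion_classes())
  ev3 <- evaluate_patch_classifier(probs, labels = labs)
  pred <- lesion_classes()[max.col(probs, ties.method = "first")]
  for (cl in lesion_classes()) {
    expect_equal(unname(ev3$sensitivity[cl]), mean(pred[labs == cl] == cl))
    expect_equal(unname(ev3$specificity[cl]), mean(pred[labs != cl] != cl))
  }
  expect_equal(ev3$accuracy, mean(pred == labs))

  # a class absent from the evaluation set yields NA metrics, not zero
  labs2 <- factor(rep("normal", 5), levels = lesion_classes())
  ev4 <- evaluate_patch_classifier(probs[1:5, ], labels = labs2)
  expect_true(is.na(ev4$sensitivity["cancer"]))
})

test_that("saliency maps are analytic gradients of the class score", {
  tr <- generate_patch_set(25, patch_size = 48, seed = 21)
  clf <- train_patch_classifier(tr, config = list(downsample_side = 4), seed = 1)
  patch <- generate_patch_set(1, patch_size = 48, seed = 22)$patches[[1]]

  # the multinomial reference class has a constant (zero) score: zero map
  ref_class <- clf$model$lev[1]
  expect_true(all(saliency_map(clf, patch, class = ref_class) == 0))

  # finite-difference check against the analytic map at step 1
  cls <- "cancer"
  sal <- saliency_map(clf, patch, class = cls)
  score0 <- slideheat:::class_scores(clf, list(patch))[, cls]
  set.seed(5)
  idx <- cbind(sample(48, 60, TRUE), sample(48, 60, TRUE))
  fd <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    g <- 0
    for (k in 1:3) {
      p2 <- patch
      p2[idx[i, 1], idx[i, 2], k] <- p2[idx[i, 1], idx[i, 2], k] + 1
      g <- max(g, abs(slideheat:::class_scores(clf, list(p2))[, cls] - score0))
    }
    fd[i] <- g
  }
  expect_gte(stats::cor(fd, sal[idx]), 0.95)
})

test_that("classifiers round-trip through the save archive", {
  tr <- generate_patch_set(10, patch_size = 32, seed = 31)
  clf <- train_patch_classifier(tr, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_patch_classifier(clf, path)
  back <- load_patch_classifier(path)
  expect_equal(predict(back, tr), predict(clf, tr))
})

test_that("stain normalization does not hurt accuracy under stain variability", {
  # spot check on two seeds; the full 5-seed sweep runs with the acceptance suite
  ref <- estimate_stain_matrix(
    generate_patch_set(1, 128, "normal", seed = 99)$patches[[1]])
  wins <- logical(2)
  for (s in 1:2) {
    tr <- generate_patch_set(60, patch_size = 128, stain_jitter = 0.25, seed = s)
    te <- generate_patch_set(60, patch_size = 128, stain_jitter = 0.25,
                             seed = s + 100)
    raw <- accuracy_of(train_patch_classifier(tr, seed = 1), te)
    norm_set <- function(ps) {
      ps$patches <- suppressWarnings(
        lapply(ps$patches, normalize_to_reference, reference = ref))
      ps
    }
    trn <- norm_set(tr); ten <- norm_set(te)
    nrm <- accuracy_of(train_patch_classifier(trn, seed = 1), ten)
    wins[s] <- nrm >= raw
  }
  expect_true(all(wins))
})
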