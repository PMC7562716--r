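# Pluggable probabilistic patch classifier: contract, reference
# implementation, evaluation metrics and gradient saliency.
#
# The contract is the probability interface every downstream stage depends
# on: predict(patches) returns one (p_normal, p_gastritis, p_cancer) triple
# per patch, summing to 1, in fixed class order; the malignancy probability
# is 1 - p_normal. The reference implementation is a multinomial logistic
# model (fit by maximum likelihood, i.e. the cross-entropy objective) on an
# area-downsampled pixel representation of the raw patch: small, fast,
# deterministic, and linear so its class-score gradients are analytic.

# Downsampled pixel features: d x d x 3 area average, scaled to [0, 1].
patch_features <- function(rasters, d) {
  X <- t(vapply(rasters, function(r) as.vector(resize_area(r, d)) / 255,
                numeric(d * d * 3)))
  colnames(X) <- paste0("px", seq_len(ncol(X)))
  X
}

#' Train the reference patch classifier
#'
#' @param patches List of h x w x 3 rasters (values 0--255), or a patch set
#'   as returned by `generate_patch_set`.
#' @param labels Factor/character labels in `lesion_classes()`; ignored when
#'   `patches` is a patch set carrying labels.
#' @param config List: `downsample_side` (pixel grid the patch is averaged to,
#'   default 8), `decay` (L2 penalty, default 0.01), `maxit` (default 300).
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @return An object of class `slideheat_patch_classifier`.
#' @export
train_patch_classifier <- function(patches, labels = NULL,
                                   config = list(), seed = 1) {
  if (is.list(patches) && !is.null(patches$patches)) {
    labels <- patches$labels
    patches <- patches$patches
  }
  cfg <- utils::modifyList(list(downsample_side = 8, decay = 0.01, maxit = 300),
                           config)
  labels <- factor(as.character(labels), levels = lesion_classes())
  present <- levels(droplevels(labels))
  if (length(present) < 2)
    stopf("training requires at least two classes; got only '%s'", present)
  set.seed(as.integer(seed))
  X <- patch_features(patches, cfg$downsample_side)
  df <- data.frame(.label = droplevels(labels), X)
  fit <- nnet::multinom(.label ~ ., data = df, trace = FALSE,
                        maxit = cfg$maxit, decay = cfg$decay,
                        MaxNWts = 100000)
  structure(list(model = fit, downsample_side = cfg$downsample_side,
                 classes = lesion_classes(), trained_classes = present,
                 metadata = list(name = "multinomial-pixel-reference",
                                 config = cfg, seed = seed,
                                 n_train = length(patches))),
            class = "slideheat_patch_classifier")
}

#' @export
print.slideheat_patch_classifier <- function(x, ...) {
  cat(sprintf("<patch classifier '%s'> trained on %d patches (%s), %dx%d features\n",
              x$metadata$name, x$metadata$n_train,
              paste(x$trained_classes, collapse = "/"),
              x$downsample_side, x$downsample_side))
  invisible(x)
}

#' Predict class probabilities for patches
#'
#' @param object A `slideheat_patch_classifier`.
#' @param patches List of rasters or a patch set.
#' @param ... Unused.
#' @return n x 3 matrix with columns (normal, gastritis, cancer); every row
#'   sums to 1 (asserted); classes absent from training get probability 0.
#' @export
predict.slideheat_patch_classifier <- function(object, patches, ...) {
  if (is.list(patches) && !is.null(patches$patches)) patches <- patches$patches
  X <- patch_features(patches, object$downsample_side)
  df <- as.data.frame(X)
  p <- stats::predict(object$model, newdata = df, type = "probs")
  if (is.null(dim(p))) {  # two-class fits return a vector
    p <- cbind(1 - p, p)
    colnames(p) <- object$model$lev
  }
  if (nrow(X) == 1 && is.null(dim(p))) p <- matrix(p, 1)
  out <- matrix(0, nrow(X), 3, dimnames = list(NULL, lesion_classes()))
  out[, colnames(p)] <- p
  bad <- abs(rowSums(out) - 1) > 1e-6
  if (any(bad)) stopf("probability triple does not sum to 1 (row %d)", which(bad)[1])
  out
}

#' Malignancy probability of patches
#'
#' The probability of not being normal mucosa, `1 - p_normal`.
#'
#' @param probs n x 3 probability matrix from `predict`.
#' @return Numeric vector in [0, 1].
#' @export
malignancy_probability <- function(probs) {
  1 - probs[, "normal"]
}

# Unnormalized class scores (multinomial linear predictors; the reference
# class scores 0). Returns n x 3 matrix over lesion_classes().
class_scores <- function(classifier, patches) {
  if (is.list(patches) && !is.null(patches$patches)) patches <- patches$patches
  X <- patch_features(patches, classifier$downsample_side)
  co <- stats::coef(classifier$model)
  if (is.null(dim(co))) co <- matrix(co, 1, dimnames = list(classifier$model$lev[2], names(co)))
  eta <- cbind(0, X %*% t(co[, -1, drop = FALSE])) +
    matrix(c(0, co[, 1]), nrow(X), nrow(co) + 1, byrow = TRUE)
  colnames(eta) <- classifier$model$lev
  out <- matrix(0, nrow(X), 3, dimnames = list(NULL, lesion_classes()))
  out[, colnames(eta)] <- eta
  out
}

#' Evaluate a patch classifier
#'
#' Computes the confusion matrix, accuracy and per-class sensitivity /
#' specificity of the argmax prediction, plus an ROC curve for the binary
#' benign-versus-cancer reading (normal and gastritis merged as benign,
#' sweeping the malignancy-probability threshold). Metrics whose class is
#' absent from the evaluation set are `NA`, not 0.
#'
#' @param classifier A `slideheat_patch_classifier`, or an n x 3 probability
#'   matrix.
#' @param patches Evaluation patches (ignored when probabilities are given).
#' @param labels True labels.
#' @param binary_malignant Classes counted as positive in the binary reading;
#'   default `c("gastritis", "cancer")` (benign = normal mucosa). Use
#'   `"cancer"` for benign-vs-cancer with gastritis merged into benign.
#' @return List with `confusion`, `accuracy`, `sensitivity`, `specificity`
#'   (per class), `binary` (list with `roc` data frame, `auc`, `sensitivity`,
#'   `specificity`, `accuracy` at threshold 0.5).
#' @export
evaluate_patch_classifier <- function(classifier, patches = NULL, labels,
                                      binary_malignant = c("gastritis", "cancer")) {
  probs <- if (is.matrix(classifier)) classifier else predict(classifier, patches)
  if (!length(labels)) stopf("evaluation set is empty")
  labels <- factor(as.character(labels), levels = lesion_classes())
  pred <- factor(lesion_classes()[max.col(probs, ties.method = "first")],
                 levels = lesion_classes())
  confusion <- table(truth = labels, predicted = pred)
  accuracy <- mean(pred == labels)
  sens <- spec <- stats::setNames(rep(NA_real_, 3), lesion_classes())
  for (cl in lesion_classes()) {
    pos <- labels == cl
    if (any(pos)) sens[cl] <- mean(pred[pos] == cl)
    if (any(!pos)) spec[cl] <- mean(pred[!pos] != cl)
  }
  # binary benign-vs-malignant reading on the malignancy probability
  truth_pos <- labels %in% binary_malignant
  mal <- if ("cancer" %in% binary_malignant && length(binary_malignant) == 1)
    probs[, "cancer"] else malignancy_probability(probs)
  binary <- NULL
  if (any(truth_pos) && any(!truth_pos)) {
    ths <- sort(unique(c(0, mal, 1)), decreasing = TRUE)
    tpr <- vapply(ths, function(t) mean(mal[truth_pos] >= t), 0)
    fpr <- vapply(ths, function(t) mean(mal[!truth_pos] >= t), 0)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    binary <- list(roc = data.frame(threshold = ths, tpr = tpr, fpr = fpr),
                   auc = auc,
                   sensitivity = mean(mal[truth_pos] >= 0.5),
                   specificity = mean(mal[!truth_pos] < 0.5),
                   accuracy = mean((mal >= 0.5) == truth_pos))
  }
  list(confusion = confusion, accuracy = accuracy, sensitivity = sens,
       specificity = spec, binary = binary)
}

#' Gradient saliency map of a patch
#'
#' Per-pixel maximum over the RGB channels of the absolute gradient of the
#' unnormalized class score with respect to the input pixels, min-max rescaled
#' to [0, 1]. For the reference classifier the gradient is analytic: the
#' score is linear in the area-downsampled pixels, so the pixel gradient is
#' the model weights back-projected through the (linear) area-average
#' operator.
#'
#' @param classifier A `slideheat_patch_classifier`.
#' @param patch h x w x 3 raster (used for its shape).
#' @param class Class whose score is differentiated.
#' @return h x w matrix in [0, 1]; identically zero when the score does not
#'   depend on the input (e.g. the reference class of the multinomial fit).
#' @export
saliency_map <- function(classifier, patch, class = "cancer") {
  stopifnot(inherits(classifier, "slideheat_patch_classifier"))
  check_rgb(patch, "patch")
  if (!(class %in% lesion_classes())) stopf("unknown class '%s'", class)
  d <- classifier$downsample_side
  h <- dim(patch)[1]; w <- dim(patch)[2]
  co <- stats::coef(classifier$model)
  if (is.null(dim(co))) co <- matrix(co, 1, dimnames = list(classifier$model$lev[2], names(co)))
  lev <- classifier$model$lev
  if (!(class %in% lev)) {
    wt <- rep(0, 3 * d * d)  # class absent from training: zero score
  } else if (class == lev[1]) {
    wt <- rep(0, 3 * d * d)  # reference class: score identically 0
  } else {
    wt <- co[class, -1]
  }
  A <- area_weights(h, d)   # feature_ij = sum_r A[i, r] * pixel / 255 ...
  B <- area_weights(w, d)
  G <- array(0, c(h, w, 3))
  for (k in 1:3) {
    Wk <- matrix(wt[((k - 1) * d * d) + seq_len(d * d)], d, d)
    G[, , k] <- t(A) %*% Wk %*% B / 255
  }
  sal <- pmax(abs(G[, , 1]), abs(G[, , 2]), abs(G[, , 3]))
  rng <- range(sal)
  if (diff(rng) < .Machine$double.eps) return(matrix(0, h, w))
  (sal - rng[1]) / diff(rng)
}

#' Save / load a patch classifier
#'
#' The classifier is serialized to a single RDS archive; its metadata
#' (training configuration, seed, class order) travels inside the object.
#'
#' @param classifier A `slideheat_patch_classifier`.
#' @param path Output `.rds` path.
#' @export
save_patch_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "slideheat_patch_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_patch_classifier
#' @export
load_patch_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "slideheat_patch_classifier"))
    stopf("'%s' does not contain a patch classifier", path)
  obj
}
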