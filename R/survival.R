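# Survival analysis: three-class outcome discretization, random-forest
# survival models on clinical and/or heatmap features, split-count feature
# importance, Kaplan-Meier curves and median-split log-rank tests.

#' Discretize right-censored survival into three outcome classes
#'
#' Classes: died within 12 months; died within 5 years but survived >= 12
#' months; survived >= 5 years (any status, since 60 observed months settle
#' the class). Patients alive with less than 60 months of follow-up are
#' excluded (`NA`): their class is indeterminable under right censoring.
#'
#' @param time Follow-up duration in months.
#' @param status 1 = died, 0 = alive at last contact.
#' @return Factor with levels `died_lt_1y`, `died_1_5y`, `survived_ge_5y`;
#'   `NA` for excluded records.
#' @export
discretize_survival <- function(time, status) {
  stopifnot(length(time) == length(status), all(time > 0))
  cls <- rep(NA_character_, length(time))
  cls[status == 1 & time < 12] <- "died_lt_1y"
  cls[status == 1 & time >= 12 & time < 60] <- "died_1_5y"
  cls[time >= 60] <- "survived_ge_5y"
  factor(cls, levels = c("died_lt_1y", "died_1_5y", "survived_ge_5y"))
}

#' Fit a random-forest survival-class model
#'
#' Discretizes the cohort into the three outcome classes, drops indeterminable
#' records, and fits a random forest on the selected feature block: clinical
#' covariates only (Model 1 style), the 44 heatmap features only (Model 2), or
#' both (Model 3). 75% of the usable records train the forest; held-out
#' accuracy is reported on the remaining 25%.
#'
#' @param records Cohort data frame with `time`, `status`, clinical covariate
#'   columns and the 44 feature columns (as from `generate_cohort`).
#' @param feature_set One of `"all"`, `"clinical"`, `"ai"`.
#' @param split Training fraction (default 0.75).
#' @param config List: `ntree` (default 500), `mtry` (default sqrt of the
#'   feature count).
#' @param seed Integer seed.
#' @return An object of class `slideheat_survival_rf`: list with `model`,
#'   `accuracy` (held-out), `confusion`, `feature_set`, `features` (column
#'   names used), `categories` (clinical/AI tag per feature).
#' @export
fit_survival_rf <- function(records, feature_set = c("all", "clinical", "ai"),
                            split = 0.75, config = list(), seed = 1) {
  feature_set <- match.arg(feature_set)
  cls <- discretize_survival(records$time, records$status)
  keep <- !is.na(cls)
  counts <- table(cls[keep])
  if (any(counts == 0))
    stopf("outcome class missing after discretization (counts: %s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  clin <- intersect(clinical_covariates(), names(records))
  ai <- intersect(feature_names_44(), names(records))
  cols <- switch(feature_set, clinical = clin, ai = ai, all = c(clin, ai))
  if (!length(cols)) stopf("no '%s' feature columns found in records", feature_set)
  X <- as.matrix(records[keep, cols, drop = FALSE])
  y <- droplevels(cls[keep])
  cfg <- utils::modifyList(list(ntree = 500, mtry = max(1, floor(sqrt(ncol(X))))),
                           config)
  set.seed(as.integer(seed))
  n <- nrow(X)
  tr <- sample(n, round(split * n))
  rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                   ntree = cfg$ntree, mtry = cfg$mtry)
  pred <- stats::predict(rf, X[-tr, , drop = FALSE])
  acc <- mean(pred == y[-tr])
  structure(list(model = rf, accuracy = acc,
                 confusion = table(truth = y[-tr], predicted = pred),
                 feature_set = feature_set, features = cols,
                 categories = ifelse(cols %in% clin, "clinical", "AI"),
                 config = cfg, seed = seed),
            class = "slideheat_survival_rf")
}

#' @export
print.slideheat_survival_rf <- function(x, ...) {
  cat(sprintf("<survival RF (%s features)> held-out accuracy %.3f on %d features\n",
              x$feature_set, x$accuracy, length(x$features)))
  invisible(x)
}

#' Split-count feature importance of a survival forest
#'
#' Importance of a feature is the number of internal tree nodes that split on
#' it, summed over all trees and normalized to sum to 1.
#'
#' @param fit A `slideheat_survival_rf` (or any object with a
#'   `randomForest` in `$model` and `features`/`categories` fields).
#' @return Data frame `feature`, `splits`, `importance`, `category`, sorted
#'   by descending importance.
#' @export
split_importance <- function(fit) {
  rf <- fit$model
  counts <- stats::setNames(rep(0L, length(fit$features)), fit$features)
  for (k in seq_len(rf$ntree)) {
    tr <- randomForest::getTree(rf, k, labelVar = TRUE)
    sv <- as.character(tr[tr$status != -1, "split var"])
    tab <- table(sv)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- sum(counts)
  out <- data.frame(feature = names(counts), splits = as.integer(counts),
                    importance = if (total > 0) counts / total else 0,
                    category = fit$categories, row.names = NULL)
  out[order(-out$importance), ]
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times, with the Greenwood
#' variance 95% confidence band on the log-survival scale. Censored records
#' contribute to the at-risk counts until their follow-up time.
#'
#' @param time Follow-up durations (months).
#' @param status 1 = died, 0 = censored.
#' @return An object of class `slideheat_km`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `lower`, `upper` (S(0) = 1 row included).
#' @export
km_estimate <- function(time, status) {
  if (!length(time)) stopf("at least one record is required")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.type = "log", conf.int = 0.95)
  structure(list(time = c(0, fit$time), n_risk = c(length(time), fit$n.risk),
                 n_event = c(0, fit$n.event), n_censor = c(0, fit$n.censor),
                 surv = c(1, fit$surv),
                 lower = c(1, fit$lower), upper = c(1, fit$upper)),
            class = "slideheat_km")
}

#' @export
print.slideheat_km <- function(x, ...) {
  cat(sprintf("<KM curve> %d time points, %d events, S(max t) = %.3f\n",
              length(x$time) - 1, sum(x$n_event), x$surv[length(x$surv)]))
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km A `slideheat_km`.
#' @param t Times (months).
#' @return S(t) as a right-continuous step function.
#' @export
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  km$surv[pmax(idx, 1)]
}

#' Plot one or more KM curves
#'
#' @param x A `slideheat_km` or list of them (named for the legend).
#' @param ci Draw the 95% confidence band.
#' @param ... Passed to `plot`.
#' @export
plot.slideheat_km <- function(x, ci = TRUE, ...) {
  curves <- if (inherits(x, "slideheat_km")) list(estimate = x) else x
  cols <- grDevices::palette.colors(length(curves) + 1)[-1]
  tmax <- max(vapply(curves, function(k) max(k$time), 0))
  graphics::plot(NULL, xlim = c(0, tmax), ylim = c(0, 1),
                 xlab = "months", ylab = "S(t)", ...)
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    if (ci)
      graphics::polygon(c(rep(k$time, each = 2)[-1], rev(rep(k$time, each = 2)[-1])),
                        c(rep(k$lower, each = 2)[-2 * length(k$time)],
                          rev(rep(k$upper, each = 2)[-2 * length(k$time)])),
                        col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(k$time, k$surv, type = "s", col = cols[i], lwd = 2)
  }
  if (length(curves) > 1)
    graphics::legend("bottomleft", names(curves), col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Export a KM curve as a data frame / CSV
#'
#' @param km A `slideheat_km`.
#' @param path Optional CSV path.
#' @return Data frame with `time`, `surv`, `lower`, `upper`, `n_risk`,
#'   `n_event`.
#' @export
km_as_data_frame <- function(km, path = NULL) {
  df <- data.frame(time = km$time, surv = km$surv, lower = km$lower,
                   upper = km$upper, n_risk = km$n_risk, n_event = km$n_event)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Median-split survival comparison for one feature
#'
#' Splits the cohort at the sample median of the feature (records equal to
#' the median go to the high group, matching the `x >= median(x)`
#' convention), estimates a KM curve per group plus the overall reference
#' curve, and tests the difference with the two-group log-rank test
#' (chi-square, 1 df).
#'
#' @param records Data frame with `time`, `status` and the feature column.
#' @param feature Feature column name.
#' @return List with `high`, `low`, `overall` (KM curves), `median`,
#'   `chisq`, `p_value`, `n_high`, `n_low`.
#' @export
median_split_curves <- function(records, feature) {
  if (!(feature %in% names(records))) stopf("feature '%s' not in records", feature)
  x <- records[[feature]]
  if (any(is.na(x))) stopf("feature '%s' has missing values", feature)
  xmed <- stats::median(x)
  hi <- x >= xmed
  if (all(hi) || !any(hi))
    stopf("degenerate split: all values of '%s' fall on one side of the median",
          feature)
  group <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
  sd <- survival::survdiff(survival::Surv(records$time, records$status) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(high = km_estimate(records$time[hi], records$status[hi]),
       low = km_estimate(records$time[!hi], records$status[!hi]),
       overall = km_estimate(records$time, records$status),
       median = xmed, chisq = unname(sd$chisq), p_value = p,
       n_high = sum(hi), n_low = sum(!hi))
}
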