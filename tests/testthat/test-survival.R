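test_that("survival discretization follows the three-class rule", {
  expect_equal(as.character(discretize_survival(6, 1)), "died_lt_1y")
  expect_equal(as.character(discretize_survival(30, 1)), "died_1_5y")
  expect_equal(as.character(discretize_survival(72, 0)), "survived_ge_5y")
  expect_equal(as.character(discretize_survival(72, 1)), "survived_ge_5y")
  expect_true(is.na(discretize_survival(30, 0)))  # alive before 60 months
  expect_equal(as.character(discretize_survival(c(3, 59, 60), c(1, 1, 0))),
               c("died_lt_1y", "died_1_5y", "survived_ge_5y"))
})

test_that("the KM estimator has its product-limit closed forms", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 1 / 3))
  expect_equal(km$time, c(0, 1, 2, 3))

  # without censoring KM equals the empirical survivor fraction
  set.seed(2)
  t <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(t, rep(1, 30))
  for (tt in c(5, 20, 40))
    expect_equal(km_survival_at(km2, tt), mean(t > tt))

  # monotone non-increasing step function starting at 1
  expect_equal(km2$surv[1], 1)
  expect_true(all(diff(km2$surv) <= 0))
})

test_that("the KM estimator is consistent for the generating exponential", {
  set.seed(3)
  n <- 200
  t <- rexp(n, 0.05)
  C <- runif(n, 0, 100)  # independent censoring, ~20% of records
  obs <- pmin(t, C)
  status <- as.integer(t <= C)
  km <- km_estimate(obs, status)
  grid <- seq(0, quantile(obs, 0.95), length.out = 50)
  expect_lte(max(abs(km_survival_at(km, grid) - exp(-0.05 * grid))), 0.08)
})

test_that("identical groups give a zero log-rank statistic", {
  df <- data.frame(time = rep(c(4, 9, 17, 30), 2),
                   status = rep(c(1, 1, 0, 1), 2),
                   f = rep(c(0, 1), each = 4))
  ms <- median_split_curves(df, "f")
  expect_equal(ms$chisq, 0, tolerance = 1e-12)
  expect_equal(ms$p_value, 1)
  expect_error(median_split_curves(data.frame(time = 1:3, status = 1,
                                              f = c(2, 2, 2)), "f"),
               "degenerate")
})

test_that("the log-rank statistic matches the hand-computed O-E form", {
  # 6 patients, two groups; events at t = 1 (B), 2 (A), 4 (A); censor at 3, 5, 6
  df <- data.frame(time = c(2, 4, 5, 1, 3, 6),
                   status = c(1, 1, 0, 1, 0, 0),
                   f = c(1, 1, 1, 0, 0, 0))
  # hand computation of sum(O - E) for group f=1 and its variance:
  # t=1: risk 6 (3 high), 1 event in low -> E_hi = 0.5, V = 0.25
  # t=2: risk 5 (3 high), 1 event in high -> E_hi = 0.6, V = 0.24
  # t=4: risk 3 (2 high), 1 event in high -> E_hi = 2/3, V = 2/9
  O <- 2; E <- 0.5 + 0.6 + 2 / 3; V <- 0.25 + 0.24 + 2 / 9
  ms <- median_split_curves(df, "f")
  expect_equal(ms$chisq, (O - E)^2 / V, tolerance = 1e-10)
  # equals the squared standardized O-E in the two-group case by construction
})

test_that("median-split power reaches 95% at hazard ratio 3 with n = 200", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rep(c(0, 1), each = 100)
    t <- rexp(200, 0.02 * 3^x)
    cens <- runif(200, 0, 100)
    df <- data.frame(time = pmin(t, cens), status = as.integer(t <= cens), f = x)
    median_split_curves(df, "f")$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("survival forests are deterministic and refuse missing classes", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 8))
  f1 <- fit_survival_rf(co, "all", config = list(ntree = 100), seed = 2)
  f2 <- fit_survival_rf(co, "all", config = list(ntree = 100), seed = 2)
  expect_equal(f1$accuracy, f2$accuracy)
  expect_s3_class(f1$confusion, "table")

  # a cohort with no late survivors cannot be fit
  co2 <- co
  co2$time <- pmin(co2$time, 40)
  expect_error(fit_survival_rf(co2, "all"), "class missing|counts")
})

test_that("split-count importance is normalized and matches a manual walk", {
  co <- generate_cohort(cohort_spec(n_patients = 250, seed = 9))
  fit <- fit_survival_rf(co, "all", config = list(ntree = 3), seed = 4)
  imp <- split_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(imp$category %in% c("clinical", "AI")))

  # manual count straight from the forest arrays
  rf <- fit$model
  manual <- table(factor(fit$features[rf$forest$bestvar[rf$forest$bestvar > 0]],
                         levels = fit$features))
  expect_equal(imp$splits[match(names(manual), imp$feature)],
               as.integer(manual))
})

test_that("a forest fed one informative column splits only on it", {
  set.seed(5)
  X <- data.frame(time = rexp(120, 0.02), status = 1,
                  age = 50, macroscopic_type = 1, distant_metastasis = 0,
                  infiltration_depth = 2)
  X$lymph_nodes <- round(120 / X$time)  # the only varying column
  fit <- fit_survival_rf(X, "clinical", config = list(ntree = 20, mtry = 2),
                         seed = 1)
  imp <- split_importance(fit)
  expect_equal(imp$importance[imp$feature == "lymph_nodes"], 1)
  expect_true(all(imp$importance[imp$feature != "lymph_nodes"] == 0))
})

test_that("a planted prognostic feature tops the importance ranking", {
  # spot check on two seeds; the 10-seed sweep runs with the acceptance suite
  tops <- vapply(1:2, function(s) {
    co <- generate_cohort(cohort_spec(n_patients = 400,
                                      hazard_coefs = c(malignant_prob_avg = 5),
                                      informative_only = TRUE, seed = s))
    fit <- fit_survival_rf(co, "ai", seed = s)
    split_importance(fit)$feature[1] == "malignant_prob_avg"
  }, TRUE)
  expect_true(all(tops))
})
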