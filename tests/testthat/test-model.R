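# Boosted severity model: training contract, relative influence, feature
# reduction, prediction, evaluation.

noise_features <- function(n, p = 6, seed = 1) {
  set.seed(seed)
  f <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(f) <- msdss_feature_names()[seq_len(p)]
  tibble::as_tibble(f)
}

fast <- msdss_params(nrounds_max = 400, shrinkage = 0.05, cv_folds = 0)

test_that("a constant target yields a constant model with zero influence", {
  f <- noise_features(60)
  m <- msdss_train(f, rep(2.5, 60), fast, seed = 1)
  expect_equal(predict(m, f), rep(2.5, 60), tolerance = 1e-6)
  expect_equal(sum(relative_influence(m)$influence), 0)
})

test_that("training is deterministic given the seed", {
  f <- noise_features(80)
  y <- f$adj_cw_per_age + rnorm(80, 0, 0.2)
  m1 <- msdss_train(f, y, fast, seed = 42)
  m2 <- msdss_train(f, y, fast, seed = 42)
  expect_identical(predict(m1, f), predict(m2, f))
  m3 <- msdss_train(f, y, fast, seed = 43)
  expect_false(identical(predict(m1, f), predict(m3, f)))
})

test_that("influences are percentages summing to 100 and reduction keeps the cut set", {
  set.seed(3)
  f <- noise_features(300, seed = 3)
  y <- 2 * f$adj_cw_per_age + 0.5 * f$measured_cw + rnorm(300, 0, 0.3)
  m <- msdss_train(f, y, fast, seed = 3)
  infl <- relative_influence(m)
  expect_equal(sum(infl$influence), 100, tolerance = 1e-6)
  expect_true(all(infl$influence >= 0))
  red <- reduce_and_retrain(m, f, y, threshold = 4)
  expect_setequal(red$feature_names,
                  infl$feature[infl$influence > 4])
  expect_true(red$reduced)
  # threshold 0 keeps everything with nonzero influence or not: all features
  red0 <- reduce_and_retrain(m, f, y, threshold = -1)
  expect_setequal(red0$feature_names, m$feature_names)
  expect_error(reduce_and_retrain(m, f, y, threshold = 101), "threshold")
})

test_that("a single-feature model concentrates all influence", {
  f <- noise_features(100)[, "adj_cw_per_age", drop = FALSE]
  y <- f$adj_cw_per_age * 2 + rnorm(100, 0, 0.1)
  m <- msdss_train(f, y, fast, seed = 1)
  expect_equal(relative_influence(m)$influence, 100, tolerance = 1e-9)
})

test_that("no feature dominates when target is independent noise", {
  # distributional check over seeds: influence stays near the uniform share
  p <- 6
  maxes <- vapply(1:10, function(s) {
    f <- noise_features(120, p = p, seed = s)
    y <- rnorm(120)
    max(relative_influence(msdss_train(f, y, fast, seed = s))$influence)
  }, numeric(1))
  expect_lt(stats::median(maxes), 3 * 100 / p)
})

test_that("monotone single-feature structure yields nondecreasing predictions", {
  f <- tibble::tibble(adj_cw_per_age = seq(0, 2, length.out = 150))
  y <- f$adj_cw_per_age^2
  m <- msdss_train(f, y, msdss_params(nrounds_max = 800, shrinkage = 0.1,
                                      cv_folds = 0), seed = 1)
  grid <- tibble::tibble(adj_cw_per_age = seq(0.1, 1.9, length.out = 40))
  pred <- predict(m, grid)
  expect_true(all(diff(pred) >= -1e-9))
})

test_that("missing feature values are routed natively at train and predict time", {
  set.seed(9)
  f <- noise_features(150, seed = 9)
  f$comris_ctd <- ifelse(runif(150) < 0.3, NA, f$comris_ctd)
  y <- f$adj_cw_per_age + 0.5 * dplyr::coalesce(f$comris_ctd, 0) +
    rnorm(150, 0, 0.2)
  m <- msdss_train(f, y, fast, seed = 9)
  new <- f[1:5, ]
  new$comris_ctd <- NA
  expect_length(predict(m, new), 5)
  expect_true(all(is.finite(predict(m, new))))
})

test_that("evaluation reports Pearson r with its p-value and guards degeneracy", {
  f <- noise_features(100)
  y <- f$adj_cw_per_age * 1.5
  m <- msdss_train(f, y, fast, seed = 2)
  ev <- msdss_evaluate(m, f, predict(m, f))
  expect_equal(ev$r, 1, tolerance = 1e-9)
  expect_equal(ev$n, 100)
  expect_error(msdss_evaluate(m, f[1:2, ], y[1:2]), "3")
  expect_error(msdss_evaluate(m, f, rep(1, 100)), "variance")
})

test_that("model predictions are near-independent of targets under the null", {
  set.seed(12)
  f_train <- noise_features(200, seed = 12)
  m <- msdss_train(f_train, rnorm(200), fast, seed = 12)
  f_new <- noise_features(1000, seed = 13)
  r <- cor(predict(m, f_new), rnorm(1000))
  expect_lt(abs(r), 0.1)
})

test_that("cross-validation selects the tree count from the configured grid", {
  set.seed(4)
  f <- noise_features(120, seed = 4)
  y <- f$adj_cw_per_age + rnorm(120, 0, 0.5)
  m <- msdss_train(f, y, msdss_params(nrounds_max = 500, shrinkage = 0.05,
                                      cv_folds = 5), seed = 4)
  expect_false(is.null(m$cv))
  expect_true(m$nrounds %in% m$cv$nrounds)
  expect_equal(m$nrounds, m$cv$nrounds[which.min(m$cv$cv_rmse)])
})

test_that("tidy, glance and save/load round trip preserve the model", {
  f <- noise_features(80)
  y <- f$adj_cw_per_age + rnorm(80, 0, 0.2)
  m <- msdss_train(f, y, fast, seed = 6)
  td <- tidy(m)
  expect_named(td, c("feature", "influence"))
  gl <- glance(m)
  expect_equal(gl$interaction_depth, 2)
  expect_equal(gl$bag_fraction, 0.5)
  prefix <- file.path(withr::local_tempdir(), "model")
  msdss_save(m, prefix)
  m2 <- msdss_load(prefix)
  expect_equal(predict(m2, f), predict(m, f), tolerance = 1e-7)
  expect_equal(m2$feature_names, m$feature_names)
  expect_s3_class(autoplot(m), "ggplot")
})
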