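# The MS-DSS severity model: a gradient-boosted regression of therapy-
# adjusted CombiWISE slopes on first-visit features, with relative-influence
# feature reduction.

#' Severity-model hyperparameters
#'
#' Defaults follow the study configuration: interaction depth 2, shrinkage
#' 0.001, half of the observations withheld from each tree (bag fraction
#' 0.5), squared-error loss, and the number of trees selected by five-fold
#' cross-validation over a multiplicative grid of candidate tree counts.
#'
#' @param interaction_depth Maximum tree depth.
#' @param shrinkage Learning rate.
#' @param bag_fraction Row subsample per tree.
#' @param nrounds_max Upper end of the tree-count grid.
#' @param nrounds_min Lower end of the tree-count grid.
#' @param grid_step Multiplicative step between candidate tree counts.
#' @param cv_folds Cross-validation folds for tree-count selection; set
#'   `cv_folds = 0` to skip selection and fit `nrounds_max` trees.
#' @return Named list of hyperparameters.
#' @export
msdss_params <- function(interaction_depth = 2, shrinkage = 0.001,
                         bag_fraction = 0.5, nrounds_max = 10000,
                         nrounds_min = 100, grid_step = 1.5, cv_folds = 5) {
  list(interaction_depth = interaction_depth, shrinkage = shrinkage,
       bag_fraction = bag_fraction, nrounds_max = nrounds_max,
       nrounds_min = nrounds_min, grid_step = grid_step, cv_folds = cv_folds)
}

.feature_matrix <- function(features, feature_names) {
  missing <- setdiff(feature_names, names(features))
  if (length(missing)) {
    abort(sprintf("features are missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(lapply(features[feature_names], as.numeric)))
  colnames(m) <- feature_names
  m
}

.nrounds_grid <- function(p) {
  g <- p$nrounds_min
  while (tail(g, 1) * p$grid_step < p$nrounds_max) {
    g <- c(g, round(tail(g, 1) * p$grid_step))
  }
  unique(c(g, p$nrounds_max))
}

#' Train the MS-DSS gradient-boosted severity model
#'
#' Fits a boosted regression-tree ensemble predicting therapy-adjusted
#' CombiWISE slopes from the engineered first-visit features. Missing feature
#' values are routed natively by the tree learner. The tree count is chosen
#' as the grid point minimising five-fold cross-validated RMSE; training is
#' deterministic given `seed` (single-threaded).
#'
#' @param features Data frame containing the columns of `feature_names`
#'   (extra columns such as `patient_id` are ignored).
#' @param target Numeric vector of therapy-adjusted slopes, finite.
#' @param params Hyperparameters, see [msdss_params()].
#' @param seed Integer seed.
#' @param feature_names Model features (default [msdss_feature_names()]).
#' @return An object of class `msdss_model`.
#' @export
msdss_train <- function(features, target, params = msdss_params(), seed = 1,
                        feature_names = intersect(msdss_feature_names(),
                                                  names(features))) {
  if (length(feature_names) == 0) abort("no usable feature columns.")
  if (nrow(features) != length(target)) {
    abort("features and target must have matching length.")
  }
  if (any(!is.finite(target))) abort("target contains non-finite values.")
  X <- .feature_matrix(features, feature_names)
  xparams <- list(max_depth = params$interaction_depth,
                  eta = params$shrinkage,
                  subsample = params$bag_fraction,
                  objective = "reg:squarederror", nthread = 1)
  dm <- xgboost::xgb.DMatrix(X, label = target, missing = NA)
  restore <- .local_seed(seed)
  on.exit(restore())

  cv_log <- NULL
  if (params$cv_folds > 1 && length(unique(target)) > 1 &&
      length(target) >= 2 * params$cv_folds) {
    cv <- xgboost::xgb.cv(params = xparams, data = dm,
                          nrounds = params$nrounds_max,
                          nfold = params$cv_folds, verbose = 0)
    log <- as.data.frame(cv$evaluation_log)
    grid <- .nrounds_grid(params)
    cv_log <- tibble(nrounds = grid,
                     cv_rmse = log$test_rmse_mean[grid])
    nrounds <- grid[which.min(cv_log$cv_rmse)]
  } else {
    nrounds <- params$nrounds_max
  }
  booster <- xgboost::xgb.train(params = xparams, data = dm,
                                nrounds = nrounds, verbose = 0)
  m <- structure(list(booster = booster, feature_names = feature_names,
                      params = params, nrounds = nrounds, cv = cv_log,
                      seed = seed, reduced = FALSE,
                      n_train = length(target)),
                 class = "msdss_model")
  m$influence <- .influence(m)
  m
}

# summed squared-error split improvements per feature across all trees,
# normalised to percentages (from the ensemble's tree dump)
.influence <- function(m) {
  infl <- setNames(rep(0, length(m$feature_names)), m$feature_names)
  dump <- tryCatch(
    as.data.frame(xgboost::xgb.model.dt.tree(model = m$booster)),
    error = function(e) NULL)
  if (!is.null(dump)) {
    splits <- dump[dump$Feature != "Leaf", , drop = FALSE]
    if (nrow(splits)) {
      gain <- tapply(splits$Gain, splits$Feature, sum)
      infl[names(gain)] <- gain / sum(gain) * 100
    }
  }
  tibble(feature = m$feature_names, influence = unname(infl)) |>
    arrange(desc(.data$influence))
}

#' Relative influence of the model's features
#'
#' Per-feature share of the total squared-error improvement contributed by
#' that feature's splits across all trees of the ensemble, normalised to
#' percentages summing to 100 (all zero when the ensemble holds no splits,
#' e.g. a constant target).
#'
#' @param m An [msdss_train()] model.
#' @return Tibble: `feature`, `influence` (percent), descending.
#' @export
relative_influence <- function(m) {
  stopifnot(inherits(m, "msdss_model"))
  m$influence
}

#' Reduce the severity model to its influential features and retrain
#'
#' Retains exactly the features whose relative influence in the fitted model
#' exceeds `threshold` percent and retrains on that subset.
#'
#' @param m A fitted [msdss_train()] model.
#' @param features,target The training data used for `m`.
#' @param threshold Relative-influence threshold in percent (default 4.0).
#' @param seed Integer seed for the retrain.
#' @return A reduced `msdss_model` (`reduced = TRUE`).
#' @export
reduce_and_retrain <- function(m, features, target, threshold = 4.0,
                               seed = m$seed) {
  stopifnot(inherits(m, "msdss_model"))
  infl <- relative_influence(m)
  keep <- infl$feature[infl$influence > threshold]
  if (length(keep) == 0) {
    abort("no feature exceeds the influence threshold; lower the threshold.")
  }
  keep <- intersect(m$feature_names, keep) # restore canonical order
  m2 <- msdss_train(features, target, params = m$params, seed = seed,
                    feature_names = keep)
  m2$reduced <- TRUE
  m2$threshold <- threshold
  m2
}

#' Predict MS-DSS scores
#'
#' MS-DSS is the model's prediction of the therapy-adjusted CombiWISE
#' progression slope (CombiWISE units per year) from cross-sectional
#' features. Missing feature values are handled by the learner's
#' missing-value routing.
#'
#' @param object An `msdss_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted slopes.
#' @export
predict.msdss_model <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata, object$feature_names)
  predict(object$booster, xgboost::xgb.DMatrix(X, missing = NA))
}

#' Evaluate a severity model against observed adjusted slopes
#'
#' @param m An `msdss_model`.
#' @param features Feature data frame.
#' @param target Observed therapy-adjusted slopes.
#' @return One-row tibble: `r` (Pearson), `p_value`, `n`.
#' @export
msdss_evaluate <- function(m, features, target) {
  pred <- predict(m, features)
  if (length(target) < 3) abort("need at least 3 paired observations.")
  if (sd(pred) == 0 || sd(target) == 0) {
    abort("correlation undefined: zero variance in predictions or targets.")
  }
  ct <- cor.test(pred, target)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(target))
}

#' @export
print.msdss_model <- function(x, ...) {
  cat(sprintf("<msdss_model>%s %d features, %d trees (depth %d, shrinkage %g), n = %d\n",
              if (x$reduced) " [reduced]" else "", length(x$feature_names),
              x$nrounds, x$params$interaction_depth, x$params$shrinkage,
              x$n_train))
  top <- head(x$influence, 5)
  cat("  top influence:",
      paste(sprintf("%s %.1f%%", top$feature, top$influence), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy the severity model's relative influences
#' @param x An `msdss_model`.
#' @param ... Unused.
#' @return Tibble: `feature`, `influence`.
#' @export
tidy.msdss_model <- function(x, ...) relative_influence(x)

#' One-row model summary
#' @param x An `msdss_model`.
#' @param ... Unused.
#' @return Tibble of hyperparameters, tree count and training size.
#' @export
glance.msdss_model <- function(x, ...) {
  tibble(n_features = length(x$feature_names), nrounds = x$nrounds,
         interaction_depth = x$params$interaction_depth,
         shrinkage = x$params$shrinkage,
         bag_fraction = x$params$bag_fraction,
         cv_folds = x$params$cv_folds, reduced = x$reduced,
         n_train = x$n_train)
}

#' Relative-influence bar chart
#' @param object An `msdss_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msdss_model <- function(object, ...) {
  df <- relative_influence(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$influence,
    y = stats::reorder(.data$feature, .data$influence))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relative influence (%)", y = NULL,
                  title = "MS-DSS feature influence") +
    ggplot2::theme_minimal()
}

#' Predicted versus observed adjusted slopes
#'
#' @param m An `msdss_model`.
#' @param features Feature data frame.
#' @param target Observed therapy-adjusted slopes.
#' @return A ggplot scatter with the identity line and Pearson r annotation.
#' @export
plot_predictions <- function(m, features, target) {
  pred <- predict(m, features)
  ev <- msdss_evaluate(m, features, target)
  ggplot2::ggplot(tibble(pred = pred, obs = target),
                  ggplot2::aes(.data$pred, .data$obs)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "MS-DSS (predicted adjusted slope, units/year)",
                  y = "observed adjusted CombiWISE slope (units/year)",
                  subtitle = sprintf("r = %.3f, p = %.3g, n = %d",
                                     ev$r, ev$p_value, ev$n)) +
    ggplot2::theme_minimal()
}
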