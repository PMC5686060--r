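# Replicated end-to-end experiment comparing the predictive power of the
# severity scales on synthetic cohorts with known ground truth.

#' Compare severity scales as predictors of future adjusted progression
#'
#' For each seed, generates a cohort, computes every cross-sectional severity
#' scale at the first visit (MSSS, ARMSS, measured CombiWISE/age,
#' therapy-adjusted CombiWISE/age), fits and adjusts the longitudinal
#' CombiWISE slopes, performs the stratified 2:1 split, trains the boosted
#' severity model on the training arm, and records the Pearson correlation of
#' each scale (and of MS-DSS) with the therapy-adjusted slopes in the
#' validation arm.
#'
#' @param config A [cohort_config()]; its `seed` is replaced per replicate.
#' @param seeds Integer vector of replicate seeds.
#' @param params Model hyperparameters for the replicates (see
#'   [msdss_params()]); the default uses a reduced tree-count grid sized for
#'   replicated runs.
#' @return Tibble: `seed`, `scale` (`MSSS`, `ARMSS`, `measured_cw_age`,
#'   `adjusted_cw_age`, `MSDSS`), `r`, `n_validation`.
#' @export
scale_experiment <- function(config = cohort_config(), seeds = 1:20,
                             params = msdss_params(nrounds_max = 2000)) {
  purrr::map(seeds, function(s) {
    config$seed <- s
    sim <- simulate_cohort(config)
    res <- run_scale_comparison(sim$cohort, seed = s, params = params,
                                efficacy = config$efficacy)
    mutate(res, seed = s, .before = 1)
  }) |> purrr::list_rbind()
}

#' Single-cohort scale comparison
#'
#' The per-cohort computation behind [scale_experiment()]: validation-arm
#' Pearson correlations of each cross-sectional severity scale against the
#' therapy-adjusted CombiWISE slopes.
#'
#' @param cohort An [ms_cohort()].
#' @param seed Integer seed for the split and model.
#' @param params See [msdss_params()].
#' @param efficacy An [efficacy_model()].
#' @return Tibble: `scale`, `r`, `n_validation`.
#' @export
run_scale_comparison <- function(cohort, seed = 1,
                                 params = msdss_params(nrounds_max = 2000),
                                 efficacy = efficacy_model()) {
  scores <- score_cohort(cohort) |>
    tidyr::pivot_wider(names_from = "scale_name", values_from = "value")
  feats <- build_features(cohort, model = efficacy)
  traj <- fit_slopes(cohort, "CombiWISE") |>
    adjust_trajectories(cohort, model = efficacy)

  df <- feats |>
    inner_join(select(traj, "patient_id", "adjusted_slope"),
               by = "patient_id") |>
    inner_join(select(scores, "patient_id", "MSSS", "ARMSS", "CW_per_age"),
               by = "patient_id")
  split <- stratified_split(df, seed = seed)
  df <- inner_join(df, split, by = "patient_id")
  train <- filter(df, .data$arm == "train")
  valid <- filter(df, .data$arm == "validation")

  model <- msdss_train(train, train$adjusted_slope, params = params,
                       seed = seed)
  r_of <- function(x) cor(x, valid$adjusted_slope)
  tibble(
    scale = c("MSSS", "ARMSS", "measured_cw_age", "adjusted_cw_age", "MSDSS"),
    r = c(r_of(valid$MSSS), r_of(valid$ARMSS),
          r_of(valid$measured_cw / valid$age), r_of(valid$adj_cw_per_age),
          r_of(predict(model, valid))),
    n_validation = nrow(valid))
}
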