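# End-to-end pipeline orchestration: ordered subcommands over a single
# config, each writing its module's artifact files plus a JSON run manifest.

#' Pipeline configuration
#'
#' A serialisable (YAML) configuration holding every constant the pipeline
#' uses: the efficacy-line coefficients and cap, reference bin widths, model
#' hyperparameters, split fraction, seeds and simulation size. Defaults
#' reproduce the published settings wherever the method states them.
#'
#' @param out_dir Directory receiving all pipeline artifacts.
#' @param cohort_dir Directory holding `demographics.csv` / `visits.csv` /
#'   `treatments.csv`; defaults to `<out_dir>/cohort` (where `simulate`
#'   writes).
#' @param seed Integer master seed.
#' @param n_patients Cohort size for the `simulate` step.
#' @param efficacy_low,efficacy_high `c(intercept, age_slope)` of the percent
#'   efficacy lines.
#' @param efficacy_cap Per-epoch efficacy cap (fraction).
#' @param msss_bin_width,armss_bin_width Reference bin widths in years.
#' @param train_fraction Training fraction of the stratified split.
#' @param model_params See [msdss_params()].
#' @param influence_threshold Relative-influence cut for the reduced model.
#' @param stability_partitions Replicates for the `stability` step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "msdss_run",
                            cohort_dir = NULL,
                            seed = 1, n_patients = 201,
                            efficacy_low = c(83.71, -1.50),
                            efficacy_high = c(206.39, -4.34),
                            efficacy_cap = 0.95,
                            msss_bin_width = 1, armss_bin_width = 5,
                            train_fraction = 2 / 3,
                            model_params = msdss_params(),
                            influence_threshold = 4.0,
                            stability_partitions = 100) {
  cfg <- as.list(environment())
  cfg$cohort_dir <- cohort_dir %||% file.path(out_dir, "cohort")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), names(cfg))) {
    cfg[[nm]] <- if (nm == "model_params") {
      utils::modifyList(msdss_params(), raw[[nm]])
    } else if (is.numeric(cfg[[nm]]) && !is.null(raw[[nm]])) {
      as.numeric(unlist(raw[[nm]]))
    } else raw[[nm]]
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.cfg_efficacy <- function(config) {
  efficacy_model(low = config$efficacy_low, high = config$efficacy_high,
                 cap = config$efficacy_cap)
}

.artifact <- function(config, ...) file.path(config$out_dir, ...)

.need_artifact <- function(config, file, prior_step) {
  path <- .artifact(config, file)
  if (!file.exists(path)) {
    abort(sprintf("missing upstream artifact '%s': run the '%s' step first.",
                  file, prior_step))
  }
  path
}

.write_manifest <- function(config, step, counts) {
  manifest <- list(step = step, seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   row_counts = counts,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("msdss")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, .artifact(config,
                                           sprintf("manifest_%s.json", step)),
                       auto_unbox = TRUE, pretty = TRUE)
}

.load_cohort <- function(config) {
  if (!file.exists(file.path(config$cohort_dir, "demographics.csv"))) {
    abort(sprintf("no cohort found in '%s': run the 'simulate' step or point cohort_dir at existing data.",
                  config$cohort_dir))
  }
  read_cohort(config$cohort_dir)
}

#' Run one pipeline step
#'
#' Steps, in their natural order: `simulate` (synthetic cohort + ground
#' truth), `score` (cross-sectional severity scales), `adjust`
#' (therapy-adjusted cross-sectional disability), `fit-slopes` (longitudinal
#' OLS slopes + therapy-adjusted slopes), `split` (features + stratified
#' partition), `train` (full + reduced severity model), `predict` (MS-DSS
#' for every patient), `evaluate` (training/validation correlations),
#' `stability` (random-partition correlation distribution). Each step writes
#' its artifact files and a `manifest_<step>.json` into the configured output
#' directory and aborts with the name of the missing prior step if run out of
#' order. A full run is reproducible from the config and seed alone.
#'
#' @param step Step name (see above).
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(step = c("simulate", "score", "adjust", "fit-slopes",
                                  "split", "train", "predict", "evaluate",
                                  "stability"),
                         config = pipeline_config()) {
  step <- match.arg(step)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  eff <- .cfg_efficacy(config)
  written <- switch(
    step,
    "simulate" = {
      sim <- simulate_cohort(cohort_config(n_patients = config$n_patients,
                                           seed = config$seed,
                                           efficacy = eff))
      write_cohort(sim$cohort, config$cohort_dir)
      truth_dir <- file.path(dirname(config$cohort_dir), "ground_truth")
      if (!dir.exists(truth_dir)) dir.create(truth_dir, recursive = TRUE)
      readr::write_csv(sim$ground_truth,
                       file.path(truth_dir, "ground_truth.csv"),
                       progress = FALSE)
      .write_manifest(config, step,
                      list(patients = n_patients(sim$cohort),
                           visits = nrow(sim$cohort$visits)))
      config$cohort_dir
    },
    "score" = {
      cohort <- .load_cohort(config)
      scores <- score_cohort(
        cohort,
        msss_ref = build_reference(cohort, "disease_duration",
                                   config$msss_bin_width),
        armss_ref = build_reference(cohort, "age", config$armss_bin_width))
      readr::write_csv(scores, .artifact(config, "scores.csv"),
                       progress = FALSE)
      .write_manifest(config, step, list(scores = nrow(scores)))
      .artifact(config, "scores.csv")
    },
    "adjust" = {
      .need_artifact(config, "scores.csv", "score")
      cohort <- .load_cohort(config)
      adj <- purrr::map(c(first = "first", last = "last"), function(w) {
        fv <- first_visits(cohort, which = w)
        cw <- compute_combiwise(fv$edss, fv$snrs, fv$t25fw_seconds,
                                fv$t25fw_fail, fv$ndh_9hpt_seconds,
                                fv$ndh_9hpt_fail)
        tr_split <- split(cohort$treatments, cohort$treatments$patient_id)
        purrr::map(seq_len(nrow(fv)), function(i) {
          ep <- tr_split[[fv$patient_id[i]]] %||% .empty_treatments()
          a <- adjust_cross_sectional(cw[i], ep, fv$visit_age[i], eff)
          tibble(patient_id = fv$patient_id[i],
                 measure = paste0("cw_", w), measured = a$measured,
                 cumulative_efficacy = a$efficacy_used,
                 adjusted = a$adjusted)
        }) |> purrr::list_rbind()
      }) |> purrr::list_rbind()
      readr::write_csv(adj, .artifact(config, "adjustments.csv"),
                       progress = FALSE)
      .write_manifest(config, step, list(adjustments = nrow(adj)))
      .artifact(config, "adjustments.csv")
    },
    "fit-slopes" = {
      .need_artifact(config, "adjustments.csv", "adjust")
      cohort <- .load_cohort(config)
      traj <- purrr::map(c("CombiWISE", "EDSS"), function(sc) {
        t <- fit_slopes(cohort, sc)
        if (sc == "CombiWISE") adjust_trajectories(t, cohort, eff) else
          mutate(t, cumulative_efficacy = NA_real_,
                 adjusted_slope = NA_real_)
      }) |> purrr::list_rbind()
      readr::write_csv(traj, .artifact(config, "trajectories.csv"),
                       progress = FALSE)
      slope_rows <- traj |>
        filter(.data$scale_name == "CombiWISE") |>
        transmute(.data$patient_id, measure = "slope",
                  measured = .data$slope, .data$cumulative_efficacy,
                  adjusted = .data$adjusted_slope)
      adj <- readr::read_csv(.artifact(config, "adjustments.csv"),
                             show_col_types = FALSE) |>
        filter(.data$measure != "slope") |>
        bind_rows(slope_rows)
      readr::write_csv(adj, .artifact(config, "adjustments.csv"),
                       progress = FALSE)
      .write_manifest(config, step, list(trajectories = nrow(traj)))
      .artifact(config, "trajectories.csv")
    },
    "split" = {
      .need_artifact(config, "trajectories.csv", "fit-slopes")
      cohort <- .load_cohort(config)
      feats <- build_features(cohort, model = eff)
      readr::write_csv(feats, .artifact(config, "features.csv"),
                       progress = FALSE)
      part <- stratified_split(feats,
                               train_fraction = config$train_fraction,
                               seed = config$seed)
      readr::write_csv(part, .artifact(config, "partition.csv"),
                       progress = FALSE)
      .write_manifest(config, step,
                      list(train = sum(part$arm == "train"),
                           validation = sum(part$arm == "validation")))
      .artifact(config, "partition.csv")
    },
    "train" = {
      .need_artifact(config, "partition.csv", "split")
      d <- .training_frame(config)
      train <- filter(d, .data$arm == "train")
      full <- msdss_train(train, train$adjusted_slope,
                          params = config$model_params, seed = config$seed)
      reduced <- reduce_and_retrain(full, train, train$adjusted_slope,
                                    threshold = config$influence_threshold)
      msdss_save(reduced, .artifact(config, "msdss_model"))
      jsonlite::write_json(
        list(full_influence = relative_influence(full),
             reduced_features = reduced$feature_names,
             threshold = config$influence_threshold),
        .artifact(config, "influence.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
      .write_manifest(config, step,
                      list(n_train = nrow(train),
                           n_features_full = length(full$feature_names),
                           n_features_reduced = length(reduced$feature_names)))
      .artifact(config, "msdss_model.ubj")
    },
    "predict" = {
      .need_artifact(config, "msdss_model.ubj", "train")
      model <- msdss_load(.artifact(config, "msdss_model"))
      feats <- readr::read_csv(.artifact(config, "features.csv"),
                               show_col_types = FALSE)
      preds <- tibble(patient_id = feats$patient_id,
                      msdss = predict(model, feats))
      readr::write_csv(preds, .artifact(config, "predictions.csv"),
                       progress = FALSE)
      .write_manifest(config, step, list(predictions = nrow(preds)))
      .artifact(config, "predictions.csv")
    },
    "evaluate" = {
      .need_artifact(config, "msdss_model.ubj", "train")
      model <- msdss_load(.artifact(config, "msdss_model"))
      d <- .training_frame(config)
      ev <- purrr::map(c(train = "train", validation = "validation"),
                       function(a) {
        dd <- filter(d, .data$arm == a)
        msdss_evaluate(model, dd, dd$adjusted_slope)
      })
      out <- list(training = as.list(ev$train),
                  validation = as.list(ev$validation))
      jsonlite::write_json(out, .artifact(config, "evaluation.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      .write_manifest(config, step, list(evaluated = nrow(d)))
      .artifact(config, "evaluation.json")
    },
    "stability" = {
      .need_artifact(config, "partition.csv", "split")
      d <- .training_frame(config)
      st <- partition_stability(d, d$adjusted_slope,
                                n_partitions = config$stability_partitions,
                                seed = config$seed,
                                params = config$model_params)
      jsonlite::write_json(as.list(st$summary),
                           .artifact(config, "stability_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      .write_manifest(config, step,
                      list(partitions = config$stability_partitions,
                           dropped = st$summary$n_dropped))
      .artifact(config, "stability_summary.json")
    })
  invisible(written)
}

.training_frame <- function(config) {
  feats <- readr::read_csv(.artifact(config, "features.csv"),
                           show_col_types = FALSE)
  traj <- readr::read_csv(.artifact(config, "trajectories.csv"),
                          show_col_types = FALSE) |>
    filter(.data$scale_name == "CombiWISE")
  part <- readr::read_csv(.artifact(config, "partition.csv"),
                          show_col_types = FALSE)
  feats |>
    inner_join(select(traj, "patient_id", "adjusted_slope"),
               by = "patient_id") |>
    inner_join(select(part, "patient_id", "arm"), by = "patient_id")
}

#' Save / load a severity model as a portable artifact
#'
#' The boosted ensemble is written as `<prefix>.ubj` (the learner's portable
#' format) with a `<prefix>.json` metadata sidecar carrying feature names,
#' hyperparameters, relative influences, seed and software versions.
#'
#' @param m An `msdss_model`.
#' @param prefix File path prefix (no extension).
#' @return `msdss_save()` the prefix invisibly; `msdss_load()` the model.
#' @export
msdss_save <- function(m, prefix) {
  stopifnot(inherits(m, "msdss_model"))
  xgboost::xgb.save(m$booster, paste0(prefix, ".ubj"))
  meta <- list(feature_names = m$feature_names, params = m$params,
               nrounds = m$nrounds, seed = m$seed, reduced = m$reduced,
               n_train = m$n_train,
               influence = relative_influence(m),
               versions = list(r = as.character(getRversion()),
                               msdss = as.character(
                                 utils::packageVersion("msdss")),
                               xgboost = as.character(
                                 utils::packageVersion("xgboost"))))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname msdss_save
#' @export
msdss_load <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- structure(list(booster = xgboost::xgb.load(paste0(prefix, ".ubj")),
                      feature_names = meta$feature_names,
                      params = meta$params, nrounds = meta$nrounds,
                      seed = meta$seed, reduced = meta$reduced,
                      n_train = meta$n_train,
                      influence = as_tibble(meta$influence)),
                 class = "msdss_model")
  m
}
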