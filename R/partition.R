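# Stratified 2:1 training/validation partitioning and repeated random-
# partition stability evaluation.

#' Stratified 2:1 training/validation split
#'
#' Patients are crossed on race, sex, and above/below-median bins of
#' therapy-adjusted CombiWISE/age and age at first visit (medians computed on
#' the full cohort; ties go to the lower bin). Within each of the resulting
#' cells, approximately two-thirds of patients are drawn uniformly without
#' replacement into the training arm (`floor(2n/3 + 0.5)`, i.e. round half
#' up), the remainder forming the validation arm. The full crossing yields up
#' to 16 cells; empty cells are skipped.
#'
#' @param features Data frame with one row per patient: `patient_id`, `race`,
#'   `sex`, `adj_cw_per_age`, `age`.
#' @param train_fraction Training fraction (default 2/3).
#' @param seed Integer seed making the draw deterministic.
#' @param ties `"lower"` (default) or `"upper"`: the bin receiving values
#'   exactly at the median.
#' @return Tibble: `patient_id`, `cell_id`, `arm` (`train`/`validation`).
#' @export
stratified_split <- function(features, train_fraction = 2 / 3, seed = 1,
                             ties = c("lower", "upper")) {
  ties <- match.arg(ties)
  if (nrow(features) == 0) abort("cannot split an empty cohort.")
  need <- c("patient_id", "race", "sex", "adj_cw_per_age", "age")
  .require_cols(features, need, "split features")
  f <- as_tibble(features)[need]
  f$cw_bin <- .median_bin(f$adj_cw_per_age, ties)
  f$age_bin <- .median_bin(f$age, ties)
  f$cell_id <- paste(f$race, f$sex, f$cw_bin, f$age_bin, sep = "/")

  withr_seed <- .local_seed(seed)
  on.exit(withr_seed())
  out <- f |>
    mutate(arm = .draw_arm(dplyr::n(), train_fraction), .by = "cell_id")
  select(out, "patient_id", "cell_id", "arm")
}

.median_bin <- function(x, ties = "lower") {
  m <- median(x, na.rm = TRUE)
  at_or_below <- if (ties == "lower") x <= m else x < m
  ifelse(at_or_below, "low", "high")
}

.draw_arm <- function(n, train_fraction) {
  n_train <- floor(n * train_fraction + 0.5)
  arm <- rep("validation", n)
  arm[sample.int(n, n_train)] <- "train"
  arm
}

# Set the RNG locally; returns a restore function.
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Random-partition stability of a severity model
#'
#' Re-partitions the cohort fully at random (non-stratified 2:1) many times;
#' for each replicate a model is trained on the training arm and the Pearson
#' correlation between its validation-arm predictions and the therapy-adjusted
#' slopes is recorded. Replicates whose model fails are dropped and counted.
#'
#' @param features Feature data frame (one row per patient, including
#'   `patient_id`).
#' @param target Named or positional numeric vector of therapy-adjusted
#'   slopes aligned with `features` rows.
#' @param n_partitions Number of random partitions.
#' @param seed Integer seed.
#' @param trainer Function `(features, target, seed)` returning an object
#'   with a `predict` method; defaults to [msdss_train()] with `params`.
#' @param params Hyperparameters passed to [msdss_train()] when the default
#'   trainer is used; see [msdss_params()].
#' @return List with `summary` (one-row tibble: `mean`, `sd`, quantiles,
#'   `n_partitions`, `n_dropped`) and `correlations` (numeric vector).
#' @export
partition_stability <- function(features, target, n_partitions = 100,
                                seed = 1, trainer = NULL,
                                params = msdss_params()) {
  stopifnot(nrow(features) == length(target))
  trainer <- trainer %||% function(f, y, s) msdss_train(f, y, params, seed = s)
  restore <- .local_seed(seed)
  on.exit(restore())
  rep_seeds <- sample.int(.Machine$integer.max, n_partitions)
  n <- nrow(features)
  cors <- rep(NA_real_, n_partitions)
  for (k in seq_len(n_partitions)) {
    set.seed(rep_seeds[k])
    idx_train <- sample.int(n, floor(2 * n / 3 + 0.5))
    res <- tryCatch({
      m <- trainer(features[idx_train, , drop = FALSE], target[idx_train],
                   rep_seeds[k])
      pred <- predict(m, features[-idx_train, , drop = FALSE])
      obs <- target[-idx_train]
      if (sd(pred) == 0 || sd(obs) == 0) 0 else cor(pred, obs)
    }, error = function(e) NA_real_)
    cors[k] <- res
  }
  ok <- !is.na(cors)
  qs <- quantile(cors[ok], c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  list(summary = tibble(mean = mean(cors[ok]), sd = sd(cors[ok]),
                        q2.5 = qs[1], q25 = qs[2], median = qs[3],
                        q75 = qs[4], q97.5 = qs[5],
                        n_partitions = n_partitions,
                        n_dropped = sum(!ok)),
       correlations = cors[ok])
}
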