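# Synthetic longitudinal MS cohort generator. Emulates the statistical
# structure the pipeline assumes -- latent per-patient untreated progression
# slopes, treatment histories with age-dependent efficacy, and noisy
# visit-level component-scale measurements that reproduce the CombiWISE
# composite exactly -- so that every pipeline stage has a ground truth.

#' Synthetic cohort generator configuration
#'
#' Marginal distributions default to the demographic and clinical moments of
#' the cohort the method was developed on (age 48.6 +/- 11.6 y truncated to
#' 23-70, onset age 37.1 +/- 11.4 y, baseline CombiWISE 30.4 +/- 17.5,
#' COMRIS-CTD 12.8 +/- 6.3, ~50% female, ~88% white, ~60% smokers,
#' follow-up span 4.49 +/- 2.90 y). The latent untreated slope couples to
#' baseline CombiWISE/age, COMRIS-CTD and therapy delay, with a right-skewed
#' centred gamma residual that leaves roughly 15% of patients improving.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; fully determines the cohort.
#' @param onset_age,first_visit_age,baseline_cw,comris Lists
#'   `(mean, sd, min, max)` of truncated-normal marginals.
#' @param comris_missing_prob Probability a patient has no MRI score.
#' @param slope_coupling List `(intercept, per_cw_age, per_comris,
#'   per_delay_year, noise_shape, noise_scale)`: the true-slope model
#'   `intercept + per_cw_age * CW0/age + per_comris * COMRIS +
#'   per_delay_year * delay + (Gamma(shape, scale) - shape*scale)`.
#' @param visit_schedule List `(span_mean, span_sd, span_min, span_max,
#'   visits_per_year)`, or fixed design via `fixed_n`/`fixed_span`
#'   (evenly spaced visits).
#' @param measurement_noise_sd Visit-level CombiWISE measurement noise (units).
#' @param exacerbation_rate Per-visit exacerbation probability.
#' @param exacerbation_bump Transient CombiWISE increase at exacerbation
#'   visits (units).
#' @param treatment_policy List: `p_past` (probability of a pre-baseline
#'   epoch), `p_past_high` (its high-efficacy share), `p_followup`
#'   (probabilities named none/low/high/both for follow-up treatment),
#'   `p_short` (probability of an additional sub-6-month epoch),
#'   `full_span` (follow-up epochs cover the whole observation window).
#' @param demographics List of category probabilities (`p_female`, `p_white`,
#'   `p_smoker`, `family_history` named probability vector).
#' @param efficacy An [efficacy_model()] used in the forward model.
#' @return A `generator_config` list.
#' @export
cohort_config <- function(
    n_patients = 201, seed = 1,
    onset_age = list(mean = 37.1, sd = 11.4, min = 8, max = Inf),
    first_visit_age = list(mean = 48.6, sd = 11.6, min = 23, max = 70),
    baseline_cw = list(mean = 30.4, sd = 17.5, min = 0, max = 100),
    comris = list(mean = 12.8, sd = 6.3, min = 0, max = Inf),
    comris_missing_prob = 0.1,
    slope_coupling = list(intercept = -0.55, per_cw_age = 0.9,
                          per_comris = 0.05, per_delay_year = 0.03,
                          noise_shape = 2, noise_scale = 0.5),
    visit_schedule = list(span_mean = 4.49, span_sd = 2.90, span_min = 1.2,
                          span_max = 12, visits_per_year = 1.2,
                          fixed_n = NULL, fixed_span = NULL),
    measurement_noise_sd = 2,
    exacerbation_rate = 0.05,
    exacerbation_bump = 8,
    treatment_policy = list(
      p_past = 0.35, p_past_high = 0.4,
      p_followup = c(none = 0.40, low = 0.25, high = 0.20, both = 0.15),
      p_short = 0.10, full_span = FALSE),
    demographics = list(
      p_female = 0.498, p_white = 0.876, p_smoker = 0.602,
      family_history = c(none = 0.672, mild = 0.139, moderate = 0.050,
                         strong = 0.080, unknown = 0.060)),
    efficacy = efficacy_model()) {
  structure(as.list(environment()), class = "generator_config")
}

# truncated normal via inverse-CDF (one uniform per draw: deterministic
# RNG-stream consumption)
.rtnorm <- function(n, mean, sd, min = -Inf, max = Inf) {
  lo <- stats::pnorm(min, mean, sd); hi <- stats::pnorm(max, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# mean and sd of a truncated normal
.tnorm_moments <- function(mean, sd, min, max) {
  a <- (min - mean) / sd; b <- (max - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  afa <- if (is.finite(a)) a * da else 0
  bfb <- if (is.finite(b)) b * db else 0
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (afa - bfb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# parent parameters such that the *truncated* distribution carries the
# target mean and sd (truncation shrinks both, so the stated cohort moments
# are matched by a slightly wider parent)
.tnorm_calibrate <- function(spec) {
  target <- c(spec$mean, spec$sd)
  obj <- function(p) {
    m <- .tnorm_moments(p[1], exp(p[2]), spec$min, spec$max)
    sum((m - target)^2)
  }
  fit <- stats::optim(c(spec$mean, log(spec$sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(mean = fit$par[1], sd = exp(fit$par[2]), min = spec$min,
       max = spec$max)
}

.round_to_grid <- function(x, grid) grid[which.min(abs(grid - x))]

#' Generate a synthetic cohort with ground truth
#'
#' Forward model, per patient: demographic and baseline draws; treatment
#' epochs before and during follow-up; a latent CombiWISE trajectory that is
#' piecewise linear in age, progressing at `true_slope * (1 - Eff)` on
#' treated segments for progressing patients (and `true_slope / (1 - Eff)`
#' for improving patients, mirroring the slope-adjustment identities in
#' reverse); visit-level targets add independent Gaussian measurement noise
#' and a transient exacerbation bump; and component scales (EDSS, SNRS,
#' T25FW, 9HPT) solved so that the composite formula reproduces each visit's
#' target value to machine precision. The measured baseline CombiWISE is the
#' untreated-equivalent baseline attenuated by the cumulative efficacy of
#' pre-baseline treatment.
#'
#' @param config A [cohort_config()].
#' @return An `ms_sim` object: list with `cohort` (an [ms_cohort()]),
#'   `ground_truth` (one row per patient: `true_slope`, `cw0_untreated`,
#'   `comris_true`, `delay_years`, `past_efficacy`, `followup_efficacy`,
#'   ...), `visit_truth` (per-visit latent and target CombiWISE), and
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "generator_config"))
  restore <- .local_seed(config$seed)
  on.exit(restore())
  n <- config$n_patients
  dg <- config$demographics
  # match the emitted marginals, not the parent, to the stated moments
  for (nm in c("onset_age", "first_visit_age", "baseline_cw", "comris")) {
    config[[nm]] <- .tnorm_calibrate(config[[nm]])
  }

  demo <- tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex = ifelse(runif(n) < dg$p_female, "female", "male"),
    race = ifelse(runif(n) < dg$p_white, "white", "other"),
    smoking = ifelse(runif(n) < dg$p_smoker, "yes", "no_or_unknown"),
    family_history = sample(names(dg$family_history), n, replace = TRUE,
                            prob = dg$family_history),
    onset_age = NA_real_)

  visits <- vector("list", n); treats <- vector("list", n)
  truth <- vector("list", n); vtruth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- .simulate_patient(demo$patient_id[i], config)
    demo$onset_age[i] <- p$onset_age
    visits[[i]] <- p$visits; treats[[i]] <- p$treatments
    truth[[i]] <- p$truth; vtruth[[i]] <- p$visit_truth
  }
  treats <- purrr::list_rbind(treats)
  if (nrow(treats) == 0) treats <- .empty_treatments()
  sim <- list(cohort = ms_cohort(demo, purrr::list_rbind(visits), treats),
              ground_truth = purrr::list_rbind(truth),
              visit_truth = purrr::list_rbind(vtruth),
              config = config)
  structure(sim, class = "ms_sim")
}

#' @export
print.ms_sim <- function(x, ...) {
  cat(sprintf("<ms_sim> seed %d\n", x$config$seed))
  print(x$cohort)
  invisible(x)
}

.simulate_patient <- function(id, config) {
  vs <- config$visit_schedule; tp <- config$treatment_policy
  cp <- config$slope_coupling

  fv_age <- .rtnorm(1, config$first_visit_age$mean, config$first_visit_age$sd,
                    config$first_visit_age$min, config$first_visit_age$max)
  onset <- .rtnorm(1, config$onset_age$mean, config$onset_age$sd,
                   config$onset_age$min, min(config$onset_age$max,
                                             fv_age - 0.2))
  cw0 <- .rtnorm(1, config$baseline_cw$mean, config$baseline_cw$sd,
                 config$baseline_cw$min, config$baseline_cw$max)
  comris <- .rtnorm(1, config$comris$mean, config$comris$sd,
                    config$comris$min, config$comris$max)
  comris_missing <- runif(1) < config$comris_missing_prob

  if (!is.null(vs$fixed_n)) {
    span <- vs$fixed_span
    ages <- fv_age + seq(0, span, length.out = vs$fixed_n)
  } else {
    span <- .rtnorm(1, vs$span_mean, vs$span_sd, vs$span_min, vs$span_max)
    n_vis <- 2 + rpois(1, span * vs$visits_per_year)
    ages <- fv_age + c(0, sort(runif(n_vis - 2, 0.05, 0.95)) * span, span)
  }
  t0 <- ages[1]; tn <- ages[length(ages)]

  epochs <- .simulate_epochs(onset, t0, tn, tp)

  delay <- if (nrow(epochs)) min(epochs$start_age) - onset else NA_real_
  noise <- rgamma(1, cp$noise_shape, scale = cp$noise_scale) -
    cp$noise_shape * cp$noise_scale
  true_slope <- cp$intercept + cp$per_cw_age * cw0 / fv_age +
    cp$per_comris * comris +
    cp$per_delay_year * (if (is.na(delay)) 0 else delay) + noise

  past <- filter(epochs, .data$end_age <= t0)
  future <- filter(epochs, .data$end_age > t0)
  past_eff <- cumulative_efficacy(past, 0, t0, config$efficacy)
  followup_eff <- cumulative_efficacy(future, t0, tn, config$efficacy)
  cw_t0 <- cw0 * (1 - past_eff)

  latent <- .latent_cw(ages, cw_t0, true_slope, future, config$efficacy)
  exac <- runif(length(ages)) < config$exacerbation_rate
  target <- latent + rnorm(length(ages), 0, config$measurement_noise_sd) +
    ifelse(exac, config$exacerbation_bump, 0)
  target <- pmin(pmax(target, 1), 95)

  comp <- as_tibble(do.call(rbind, lapply(target, .decompose_cw)))
  comp$t25fw[comp$t25fw_fail == 1] <- NA_real_

  list(
    onset_age = onset,
    visits = tibble(
      patient_id = id, visit_age = ages, edss = comp$edss, snrs = comp$snrs,
      t25fw_seconds = comp$t25fw, t25fw_fail = comp$t25fw_fail,
      ndh_9hpt_seconds = comp$hpt, ndh_9hpt_fail = comp$hpt_fail,
      exacerbation = as.numeric(exac),
      comris_ctd = if (comris_missing) NA_real_ else comris),
    treatments = if (nrow(epochs)) mutate(epochs, patient_id = id,
                                          .before = 1) else NULL,
    truth = tibble(
      patient_id = id, true_slope = true_slope, cw0_untreated = cw0,
      cw_measured_t0 = cw_t0, comris_true = comris,
      comris_missing = comris_missing, onset_age = onset,
      first_visit_age = fv_age, span_years = tn - t0,
      n_visits = length(ages), delay_years = delay,
      past_efficacy = past_eff, followup_efficacy = followup_eff),
    visit_truth = tibble(patient_id = id, visit_age = ages,
                         latent_cw = latent, target_cw = target,
                         exacerbation = as.numeric(exac)))
}

.simulate_epochs <- function(onset, t0, tn, tp) {
  epochs <- .empty_treatments()[c("start_age", "end_age", "efficacy_class")]
  if (runif(1) < tp$p_past && onset < t0 - 1) {
    end <- runif(1, onset + 0.6, t0 - 0.1)
    start <- max(onset + 0.05, end - runif(1, 0.5, 8))
    cls <- if (runif(1) < tp$p_past_high) "high" else "low"
    epochs <- add_row(epochs, start_age = start, end_age = end,
                      efficacy_class = cls)
  }
  type <- sample(names(tp$p_followup), 1, prob = tp$p_followup)
  span <- tn - t0
  if (tp$full_span && type != "none") {
    cls <- if (type == "both") sample(c("low", "high"), 1) else type
    epochs <- add_row(epochs, start_age = t0, end_age = tn,
                      efficacy_class = cls)
  } else if (type %in% c("low", "high")) {
    start <- t0 + runif(1, 0, 0.4 * span)
    end <- min(start + runif(1, 0.5, span), tn)
    epochs <- add_row(epochs, start_age = start, end_age = end,
                      efficacy_class = type)
  } else if (type == "both") {
    mid <- t0 + span * runif(1, 0.4, 0.6)
    gap <- min(0.3, 0.05 * span)
    cls <- sample(c("low", "high"))
    epochs <- add_row(epochs, start_age = t0, end_age = mid - gap,
                      efficacy_class = cls[1])
    epochs <- add_row(epochs, start_age = mid + gap, end_age = tn,
                      efficacy_class = cls[2])
  }
  # occasional short-lived DMT (side effects / non-response), before baseline
  if (runif(1) < tp$p_short) {
    s <- t0 - 1; e <- s + runif(1, 0.1, 0.45)
    clear <- !nrow(epochs) ||
      all(e <= epochs$start_age | s >= epochs$end_age)
    if (s > onset && clear) {
      epochs <- add_row(epochs, start_age = s, end_age = e,
                        efficacy_class = sample(c("low", "high"), 1))
    }
  }
  arrange(epochs, .data$start_age)
}

# latent CombiWISE at the visit ages: piecewise linear in age, attenuated on
# treated segments (forward counterpart of the slope-adjustment identities)
.latent_cw <- function(ages, cw_t0, true_slope, epochs, model) {
  t0 <- ages[1]
  bounds <- sort(unique(c(ages[1], ages[length(ages)],
                          pmax(pmin(c(epochs$start_age, epochs$end_age),
                                    ages[length(ages)]), t0))))
  segs <- tibble(from = head(bounds, -1), to = tail(bounds, -1))
  segs$eff <- vapply(seq_len(nrow(segs)), function(i) {
    if (!nrow(epochs)) return(0)
    hit <- epochs$start_age <= segs$from[i] + 1e-12 &
      epochs$end_age >= segs$to[i] - 1e-12
    if (!any(hit)) return(0)
    epoch_efficacy(max(epochs$start_age[hit][1], t0),
                   min(epochs$end_age[hit][1], ages[length(ages)]),
                   epochs$efficacy_class[hit][1], model)
  }, numeric(1))
  segs$obs_slope <- if (true_slope > 0) true_slope * (1 - segs$eff) else
    true_slope / (1 - segs$eff)
  cum <- cumsum(c(0, segs$obs_slope * (segs$to - segs$from)))
  vapply(ages, function(a) {
    i <- findInterval(a, bounds, rightmost.closed = TRUE)
    i <- min(i, nrow(segs))
    cw_t0 + cum[i] + segs$obs_slope[i] * (a - segs$from[i])
  }, numeric(1))
}

# Solve component scales so the composite reproduces `target` exactly:
# EDSS drawn on its legal grid near a disability-matched value, the peg time
# jittered on a realistic curve, SNRS solved and rounded to its integer
# grid, and the walk time absorbing the remaining residual in closed form.
.decompose_cw <- function(target) {
  grid <- setdiff(edss_grid(), 10)
  for (attempt in seq_len(30)) {
    edss <- .round_to_grid(
      (target - 2.5) / 9.75 + rnorm(1, 0, max(0.8 - attempt * 0.1, 0.1)),
      grid)
    hpt <- min(max(exp(log(17) + 0.16 * edss + rnorm(1, 0, 0.15)), 12), 290)
    snrs <- round(min(max(98 - 0.95 * target + rnorm(1, 0, 4), 0), 100))
    for (k in seq_len(80)) {
      lt25 <- (target - .cw_coef[["intercept"]] -
                 .cw_coef[["edss"]] * edss - .cw_coef[["snrs"]] * snrs -
                 .cw_coef[["log2_hpt"]] * log2(hpt)) / .cw_coef[["log2_t25"]]
      t25 <- 2^lt25
      if (t25 >= 1.5 && t25 <= 180) {
        return(c(edss = edss, snrs = snrs, t25fw = t25, t25fw_fail = 0,
                 hpt = hpt, hpt_fail = 0))
      }
      snrs_new <- snrs + if (t25 > 180) -4 else 4
      snrs_new <- min(max(snrs_new, 0), 100)
      if (snrs_new == snrs) break
      snrs <- snrs_new
    }
    # SNRS grid exhausted: very high targets fail the walk test instead,
    # the peg time absorbing the residual
    lhpt <- (target - .cw_coef[["intercept"]] - .cw_coef[["edss"]] * edss -
               .cw_coef[["snrs"]] * snrs -
               .cw_coef[["log2_t25"]] * log2(cw_time_limits[["t25fw"]]) -
               .cw_coef[["t25_fail"]]) / .cw_coef[["log2_hpt"]]
    hptf <- 2^lhpt
    if (hptf >= 1 && hptf <= 300) {
      return(c(edss = edss, snrs = snrs, t25fw = NA_real_,
               t25fw_fail = 1, hpt = hptf, hpt_fail = 0))
    }
  }
  abort(sprintf("component decomposition infeasible for CombiWISE %.2f",
                target))
}
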