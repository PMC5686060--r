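# Synthetic cohort generator: determinism, composite-consistency, slope
# recovery, calibration, and the exacerbation mechanism.

untreated_config <- function(n, seed, noise = 0, fixed_n = NULL,
                             fixed_span = NULL, exac = 0) {
  cohort_config(
    n_patients = n, seed = seed, measurement_noise_sd = noise,
    exacerbation_rate = exac,
    treatment_policy = list(p_past = 0, p_past_high = 0,
                            p_followup = c(none = 1, low = 0, high = 0,
                                           both = 0),
                            p_short = 0, full_span = FALSE),
    visit_schedule = list(span_mean = 4.49, span_sd = 2.90, span_min = 1.2,
                          span_max = 12, visits_per_year = 1.2,
                          fixed_n = fixed_n, fixed_span = fixed_span))
}

test_that("identical config and seed give byte-identical cohort files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cohort_config(n_patients = 30, seed = 8))$cohort, d1)
  write_cohort(simulate_cohort(cohort_config(n_patients = 30, seed = 8))$cohort, d2)
  for (f in c("demographics.csv", "visits.csv", "treatments.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # different seed changes the cohort
  s3 <- simulate_cohort(cohort_config(n_patients = 30, seed = 9))
  expect_false(identical(readLines(file.path(d1, "visits.csv")),
                         readr::format_csv(s3$cohort$visits)))
})

test_that("emitted components reproduce the per-visit composite targets exactly", {
  sim <- simulate_cohort(cohort_config(n_patients = 60, seed = 2))
  v <- sim$cohort$visits
  cw <- compute_combiwise(v$edss, v$snrs, v$t25fw_seconds, v$t25fw_fail,
                          v$ndh_9hpt_seconds, v$ndh_9hpt_fail)
  expect_equal(cw, sim$visit_truth$target_cw, tolerance = 1e-12)
  expect_true(all(v$edss %in% edss_grid()))
  expect_true(all(v$snrs == round(v$snrs)))
})

test_that("noiseless untreated trajectories return the true slope exactly", {
  sim <- simulate_cohort(untreated_config(25, seed = 4))
  fits <- fit_slopes(sim$cohort, "CombiWISE")
  j <- dplyr::inner_join(fits, sim$ground_truth, by = "patient_id") |>
    dplyr::filter(patient_id %in% interior_ids(sim))
  expect_gt(nrow(j), 15)
  expect_equal(j$slope, j$true_slope, tolerance = 1e-9)
  j3 <- dplyr::filter(j, n_visits.x >= 3)   # R^2 undefined on 2-point fits
  expect_equal(j3$r_squared, rep(1, nrow(j3)), tolerance = 1e-9)
})

test_that("noiseless treated full-span trajectories invert to the true slope", {
  cfg <- untreated_config(40, seed = 6)
  cfg$treatment_policy <- list(p_past = 0, p_past_high = 0,
                               p_followup = c(none = 0.2, low = 0.4,
                                              high = 0.3, both = 0.1),
                               p_short = 0, full_span = TRUE)
  sim <- simulate_cohort(cfg)
  traj <- adjust_trajectories(fit_slopes(sim$cohort, "CombiWISE"),
                              sim$cohort, cfg$efficacy)
  j <- dplyr::inner_join(traj, sim$ground_truth, by = "patient_id") |>
    dplyr::filter(patient_id %in% interior_ids(sim))
  expect_gt(nrow(j), 20)
  expect_equal(j$adjusted_slope, j$true_slope, tolerance = 1e-9)
  treated <- j$followup_efficacy > 0
  expect_true(any(treated))
  expect_true(all(j$adjusted_slope[treated] >= j$slope[treated]))
})

test_that("slope-estimate spread shrinks with more visits per patient", {
  err_for <- function(n_vis) {
    sim <- simulate_cohort(untreated_config(150, seed = 10, noise = 2,
                                            fixed_n = n_vis, fixed_span = 4))
    j <- dplyr::inner_join(fit_slopes(sim$cohort, "CombiWISE"),
                           sim$ground_truth, by = "patient_id")
    sd(j$slope - j$true_slope)
  }
  expect_gt(err_for(3), err_for(10))
})

test_that("seed-1 cohort reproduces the target population moments", {
  sim <- simulate_cohort(cohort_config(n_patients = 201, seed = 1))
  gt <- sim$ground_truth
  rv <- retained_visits(sim$cohort)
  fv <- dplyr::slice_min(dplyr::filter(rv, !is.na(combiwise)), visit_age,
                         n = 1, by = "patient_id", with_ties = FALSE)
  rel <- function(x, target) abs(x - target) / target
  expect_lt(rel(mean(fv$visit_age), 48.6), 0.15)
  expect_lt(rel(sd(fv$visit_age), 11.6), 0.15)
  expect_lt(rel(mean(fv$combiwise), 30.4), 0.15)
  expect_lt(rel(sd(fv$combiwise), 17.5), 0.15)
  expect_lt(rel(mean(gt$comris_true), 12.8), 0.15)
  expect_lt(rel(sd(gt$comris_true), 6.3), 0.15)
  # a realistic minority of improving patients
  expect_gt(mean(gt$true_slope < 0), 0.03)
  expect_lt(mean(gt$true_slope < 0), 0.35)
})

test_that("exacerbation visits carry a bump and are excluded from slopes", {
  cfg <- untreated_config(80, seed = 12, noise = 0, exac = 0.25)
  sim <- simulate_cohort(cfg)
  v <- sim$cohort$visits
  expect_gt(sum(v$exacerbation), 0)
  # flagged visits sit above the latent trajectory by the configured bump
  vt <- sim$visit_truth
  bump <- vt$target_cw - vt$latent_cw
  flagged <- vt$exacerbation == 1
  unclipped <- vt$target_cw > 1 & vt$target_cw < 95
  expect_equal(bump[flagged & unclipped],
               rep(8, sum(flagged & unclipped)), tolerance = 1e-9)
  expect_equal(bump[!flagged & unclipped],
               rep(0, sum(!flagged & unclipped)), tolerance = 1e-9)
  # with exclusion, fits still recover true slopes on the noiseless data
  fits <- fit_slopes(sim$cohort, "CombiWISE")
  j <- dplyr::inner_join(fits, sim$ground_truth, by = "patient_id") |>
    dplyr::filter(patient_id %in% interior_ids(sim, hi = 86.9))
  expect_gt(nrow(j), 40)
  expect_equal(j$slope, j$true_slope, tolerance = 1e-9)
})

test_that("generated cohorts always pass full input validation", {
  for (s in c(31, 32)) {
    sim <- simulate_cohort(cohort_config(n_patients = 40, seed = s))
    expect_silent(validate_cohort(sim$cohort))
  }
})
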