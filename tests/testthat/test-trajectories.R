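# Eligibility rules, per-patient OLS slopes, therapy-adjusted trajectories,
# and the paired R^2 comparison.

cohort_with_ages <- function(ages_list, exac_list = NULL) {
  n <- length(ages_list)
  ids <- sprintf("T%02d", seq_len(n))
  visits <- purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    ex <- if (is.null(exac_list)) rep(0, length(ages_list[[i]])) else
      exac_list[[i]]
    visit_row(ids[i], ages_list[[i]], exacerbation = ex)
  }))
  demo <- purrr::list_rbind(purrr::map(ids, demo_row))
  ms_cohort(demo, visits, empty_epochs())
}

test_that("eligibility implements both visit-count/span arms after exclusion", {
  cohort <- cohort_with_ages(
    list(c(50.0, 50.4, 50.6),          # 3 visits, span 0.6 -> no
         c(40.0, 43.2),                # 2 visits, span 3.2 -> yes
         c(50, 50.5, 51.0),            # 3 visits, span 1.0 -> yes
         c(50, 51, 51.5, 52)),         # 4 visits but 2 exacerbations -> span 1.5, n 2 -> no
    exac_list = list(c(0, 0, 0), c(0, 0), c(0, 0, 0), c(0, 1, 1, 0)))
  el <- eligible_patients(cohort)
  expect_equal(el$eligible, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(el$n_visits[4], 2)
  expect_equal(el$span_years[4], 2)
})

test_that("OLS slopes, intercepts and R^2 match closed forms", {
  # exact line: CombiWISE moves via SNRS (snrs 70, 65, 60 -> cw +0.407*5/step)
  demo <- demo_row("A")
  visits <- visit_row("A", c(50, 51, 52), snrs = c(70, 65, 60))
  fit <- fit_slopes(ms_cohort(demo, visits, empty_epochs()), "CombiWISE")
  expect_equal(fit$slope, 0.407 * 5)
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$n_visits, 3L)
  expect_equal(fit$span_years, 2)

  # three-point fit with known closed form: values 10, 13, 14 at ages
  # 50, 51, 52 give slope 2 and R^2 = 12/13 (hand OLS arithmetic); the
  # walk time carries the value through the composite
  vals <- c(10, 13, 14)
  x <- c(50, 51, 52)
  t25 <- 2^((vals - (33.166 - 0.407 * 100 + 1.305 * log2(16))) / 2.409)
  visits2 <- visit_row("B", x, edss = 0, snrs = 100, t25fw_seconds = t25,
                       ndh_9hpt_seconds = 16)
  cohort2 <- ms_cohort(demo_row("B"), visits2, empty_epochs())
  expect_equal(retained_visits(cohort2)$combiwise, vals)
  fit2 <- fit_slopes(cohort2, "CombiWISE")
  expect_equal(fit2$slope, 2.0)
  expect_equal(fit2$r_squared, 12 / 13)
  expect_equal(fit2$intercept, 12.333333 - 2, tolerance = 1e-6)

  # constant EDSS: slope 0, R^2 undefined
  visits3 <- visit_row("C", c(50, 51, 52), edss = 4)
  fit3 <- fit_slopes(ms_cohort(demo_row("C"), visits3, empty_epochs()), "EDSS")
  expect_equal(fit3$slope, 0)
  expect_true(is.na(fit3$r_squared))
})

test_that("slopes are invariant to age shifts; R^2 to affine response scaling", {
  set.seed(5)
  x <- c(50, 51.2, 52.5, 54)
  y <- 10 + 1.5 * (x - 50) + rnorm(4, 0, 0.5)
  f1 <- lm(y ~ x); f2 <- lm(y ~ I(x + 7))
  expect_equal(unname(coef(f1)[2]), unname(coef(f2)[2]))
  y2 <- 3 + 2 * y
  expect_equal(summary(lm(y ~ x))$r.squared, summary(lm(y2 ~ x))$r.squared)
})

test_that("exacerbation exclusion removes exactly the flagged visits", {
  ages <- c(50, 50.6, 51, 51.7, 52)
  exac <- c(0, 1, 0, 1, 0)
  cohort <- cohort_with_ages(list(ages), list(exac))
  rv <- retained_visits(cohort)
  expect_equal(rv$visit_age, ages[exac == 0])
})

test_that("slope estimates are unbiased on noisy linear trajectories", {
  sim <- simulate_cohort(cohort_config(
    n_patients = 400, seed = 9,
    treatment_policy = list(p_past = 0, p_past_high = 0,
                            p_followup = c(none = 1, low = 0, high = 0,
                                           both = 0),
                            p_short = 0, full_span = FALSE),
    exacerbation_rate = 0,
    visit_schedule = list(fixed_n = 5, fixed_span = 4)))
  fits <- fit_slopes(sim$cohort, "CombiWISE")
  j <- dplyr::inner_join(fits, sim$ground_truth, by = "patient_id")
  err <- j$slope - j$true_slope
  se <- sd(err) / sqrt(nrow(j))
  expect_lt(abs(mean(err)), 2 * se)
})

test_that("adjusted trajectories recover untreated slopes from treated data", {
  m <- flat_efficacy(low_pct = 25)
  # treated for the whole window at efficacy 0.25: observed slope 1.5 * 0.75
  demo <- demo_row("A")
  snrs_for <- function(target) (33.166 + 3.803 * 4 + 2.409 * log2(8) +
                                  1.305 * log2(32) - target) / 0.407
  true_slope <- 0.407 * 2
  obs <- true_slope * 0.75
  targets <- 30 + obs * (0:2)
  visits <- visit_row("A", c(50, 51, 52), snrs = snrs_for(targets))
  cohort <- ms_cohort(demo, visits, epoch_row("A", 50, 52, "low"))
  traj <- adjust_trajectories(fit_slopes(cohort, "CombiWISE"), cohort, m)
  expect_equal(traj$cumulative_efficacy, 0.25)
  expect_equal(traj$adjusted_slope, true_slope, tolerance = 1e-9)
  # untreated patient: adjustment is the identity
  cohort0 <- ms_cohort(demo, visits, empty_epochs())
  traj0 <- adjust_trajectories(fit_slopes(cohort0, "CombiWISE"), cohort0, m)
  expect_equal(traj0$adjusted_slope, traj0$slope)
})

test_that("paired R^2 summary handles identical, shifted and noisy inputs", {
  f <- function(ids, r2) tibble::tibble(patient_id = ids, r_squared = r2)
  ids <- sprintf("P%d", 1:6)
  same <- paired_r2_summary(f(ids, seq(0.2, 0.7, 0.1)),
                            f(ids, seq(0.2, 0.7, 0.1)))
  expect_equal(same$mean_diff, 0)
  expect_true(same$conf_low <= 0 && same$conf_high >= 0)
  shift <- paired_r2_summary(f(ids, seq(0.2, 0.7, 0.1) + 0.1),
                             f(ids, seq(0.2, 0.7, 0.1)))
  expect_equal(shift$mean_diff, 0.1)
  expect_equal(shift$conf_low, 0.1)   # zero-variance differences: degenerate CI
  # undefined R^2 rows are dropped and counted
  drop <- paired_r2_summary(f(ids, c(NA, seq(0.3, 0.7, 0.1))),
                            f(ids, seq(0.2, 0.7, 0.1)))
  expect_equal(drop$n_dropped, 1)
  expect_equal(drop$n, 5)
  expect_error(paired_r2_summary(f("X", 0.5), f("Y", 0.5)), "overlap")
})

test_that("CombiWISE fits explain more variance than EDSS fits on synthetic data", {
  sim <- simulate_cohort(cohort_config(n_patients = 150, seed = 21))
  cw <- fit_slopes(sim$cohort, "CombiWISE")
  ed <- fit_slopes(sim$cohort, "EDSS")
  res <- paired_r2_summary(cw, ed)
  expect_gt(res$mean_diff, 0)
})
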