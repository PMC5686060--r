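# Per-patient disability trajectories: eligibility rules, exacerbation-visit
# exclusion, OLS progression slopes, and therapy adjustment of slopes.

#' Per-visit scale values with exacerbation exclusion applied
#'
#' Returns the cohort's non-exacerbation visits with a `combiwise` column
#' (NA where the component scales do not allow computation). This is the
#' visit set on which eligibility and slopes are defined.
#'
#' @param cohort An [ms_cohort()].
#' @return Tibble of retained visits plus `combiwise`.
#' @export
retained_visits <- function(cohort) {
  v <- filter(cohort$visits, .data$exacerbation == 0)
  computable <- !is.na(v$edss) & !is.na(v$snrs) &
    (!is.na(v$t25fw_seconds) | v$t25fw_fail == 1) &
    (!is.na(v$ndh_9hpt_seconds) | v$ndh_9hpt_fail == 1)
  v$combiwise <- NA_real_
  if (any(computable)) {
    vc <- v[computable, ]
    v$combiwise[computable] <- compute_combiwise(
      vc$edss, vc$snrs, vc$t25fw_seconds, vc$t25fw_fail,
      vc$ndh_9hpt_seconds, vc$ndh_9hpt_fail)
  }
  v
}

#' Longitudinal eligibility of each patient
#'
#' A patient enters the longitudinal analysis with either three or more
#' non-exacerbation visits with computable CombiWISE spanning at least 1
#' year, or two or more such visits spanning at least 3 years. Exacerbation
#' visits are excluded before counting.
#'
#' @param cohort An [ms_cohort()].
#' @return Tibble: `patient_id`, `n_visits`, `span_years`, `eligible`.
#' @export
eligible_patients <- function(cohort) {
  rv <- retained_visits(cohort) |> filter(!is.na(.data$combiwise))
  out <- cohort$demographics["patient_id"] |>
    left_join(summarise(rv, n_visits = dplyr::n(),
                        span_years = max(.data$visit_age) - min(.data$visit_age),
                        .by = "patient_id"),
              by = "patient_id") |>
    mutate(n_visits = coalesce(.data$n_visits, 0L),
           span_years = coalesce(.data$span_years, 0))
  mutate(out, eligible =
           (.data$n_visits >= 3 & .data$span_years >= 1) |
           (.data$n_visits >= 2 & .data$span_years >= 3))
}

#' Per-patient OLS progression slopes
#'
#' Fits, for every eligible patient, an ordinary least-squares regression of
#' the scale value on visit age over the retained (non-exacerbation,
#' computable) visits. The intercept is reported as the fitted value at the
#' first retained visit age. R^2 is defined only when residual variation is
#' defined (at least 3 visits and a nonconstant response); otherwise `NA`.
#'
#' @param cohort An [ms_cohort()].
#' @param scale_name `"CombiWISE"` or `"EDSS"`.
#' @param keep_ineligible Keep patients failing the eligibility rule but
#'   still having >= 2 usable visits (default `FALSE`).
#' @return Tibble: `patient_id`, `scale_name`, `slope`, `intercept`,
#'   `r_squared`, `n_visits`, `span_years`.
#' @export
fit_slopes <- function(cohort, scale_name = c("CombiWISE", "EDSS"),
                       keep_ineligible = FALSE) {
  scale_name <- match.arg(scale_name)
  rv <- retained_visits(cohort)
  rv$value <- if (scale_name == "CombiWISE") rv$combiwise else rv$edss
  rv <- filter(rv, !is.na(.data$value))
  elig <- eligible_patients(cohort)
  keep <- if (keep_ineligible) elig$patient_id else
    elig$patient_id[elig$eligible]
  rv <- filter(rv, .data$patient_id %in% keep)

  rv |>
    summarise(.fit_one(.data$visit_age, .data$value), .by = "patient_id") |>
    filter(!is.na(.data$slope)) |>
    mutate(scale_name = scale_name, .after = "patient_id")
}

.fit_one <- function(age, value) {
  if (length(age) < 2) {
    return(tibble(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, n_visits = length(age),
                  span_years = if (length(age)) diff(range(age)) else 0))
  }
  fit <- lm(value ~ age)
  sst <- sum((value - mean(value))^2)
  r2 <- if (length(age) >= 3 && sst > 0) {
    1 - sum(stats::residuals(fit)^2) / sst
  } else NA_real_
  tibble(slope = unname(coef(fit)[2]),
         intercept = unname(predict(fit, data.frame(age = min(age)))),
         r_squared = r2, n_visits = length(age),
         span_years = diff(range(age)))
}

#' Adjust fitted CombiWISE slopes for therapy received during follow-up
#'
#' For each fitted trajectory, computes the duration-weighted cumulative
#' efficacy of treatment over the patient's first-to-last retained visit
#' window and applies [adjust_slope()], giving the progression slope the
#' patient would have shown untreated.
#'
#' @param trajectories Output of [fit_slopes()] (CombiWISE scale).
#' @param cohort The same [ms_cohort()].
#' @param model An [efficacy_model()].
#' @return `trajectories` with columns `cumulative_efficacy` and
#'   `adjusted_slope` added.
#' @export
adjust_trajectories <- function(trajectories, cohort,
                                model = efficacy_model()) {
  if (!all(trajectories$scale_name == "CombiWISE")) {
    abort("therapy adjustment is defined for CombiWISE slopes.")
  }
  rv <- retained_visits(cohort) |> filter(!is.na(.data$combiwise))
  win <- summarise(rv, t0 = min(.data$visit_age), tn = max(.data$visit_age),
                   .by = "patient_id")
  tr_split <- split(cohort$treatments, cohort$treatments$patient_id)
  out <- left_join(trajectories, win, by = "patient_id")
  out$cumulative_efficacy <- vapply(seq_len(nrow(out)), function(i) {
    ep <- tr_split[[out$patient_id[i]]]
    if (is.null(ep)) return(0)
    cumulative_efficacy(ep, out$t0[i], out$tn[i], model)
  }, numeric(1))
  out$adjusted_slope <- adjust_slope(out$slope, out$cumulative_efficacy)
  select(out, -"t0", -"tn")
}

#' Paired comparison of per-patient R^2 between two scales
#'
#' Pairs each patient's CombiWISE-fit R^2 with the EDSS-fit R^2 and
#' summarises the difference (CombiWISE minus EDSS) with a mean and a 95%
#' paired-t confidence interval. Patients with an undefined R^2 on either
#' scale (fewer than 3 visits or a constant response) are dropped from the
#' comparison and counted in `n_dropped`.
#'
#' @param fits_cw,fits_edss Outputs of [fit_slopes()] for the two scales.
#' @return One-row tibble: `mean_diff`, `conf_low`, `conf_high`, `p_value`,
#'   `n`, `n_dropped`, plus the per-patient difference vector in the
#'   `differences` attribute.
#' @export
paired_r2_summary <- function(fits_cw, fits_edss) {
  j <- inner_join(select(fits_cw, "patient_id", r2_cw = "r_squared"),
                  select(fits_edss, "patient_id", r2_edss = "r_squared"),
                  by = "patient_id")
  if (nrow(j) == 0) abort("no overlapping patients between the two fit sets.")
  ok <- !is.na(j$r2_cw) & !is.na(j$r2_edss)
  d <- j$r2_cw[ok] - j$r2_edss[ok]
  if (!length(d)) abort("no patients with defined R^2 on both scales.")
  if (length(d) >= 2 && sd(d) > 1e-10 * max(1, abs(mean(d)))) {
    tt <- t.test(d)
    out <- tibble(mean_diff = unname(tt$estimate),
                  conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                  p_value = tt$p.value, n = length(d),
                  n_dropped = sum(!ok))
  } else {
    out <- tibble(mean_diff = mean(d), conf_low = mean(d),
                  conf_high = mean(d), p_value = NA_real_, n = length(d),
                  n_dropped = sum(!ok))
  }
  attr(out, "differences") <- d
  out
}
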