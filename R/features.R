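# Candidate feature engineering for the severity model: everything is
# computed from data at or before the anchor visit, except the follow-up
# cumulative efficacy which summarises the treatment actually received over
# the observation window.

#' Feature columns used by the severity model
#' @return Character vector of model feature names, in canonical order.
#' @export
msdss_feature_names <- function() {
  c("adj_cw_per_age", "measured_cw", "comris_ctd",
    "onset_to_first_therapy_years", "adj_minus_measured_cw", "age",
    "family_history", "sex", "race", "smoking", "n_short_dmts",
    "cumulative_efficacy_followup", "therapy_type")
}

#' Build the candidate feature set for the severity model
#'
#' One row per patient, anchored at the first (default) or last
#' non-exacerbation visit with computable CombiWISE. Cross-sectional
#' disability is therapy-adjusted over the birth-to-anchor window; the
#' follow-up cumulative efficacy is computed over the first-to-last retained
#' visit window. Missing values (COMRIS-CTD, never-treated therapy delay,
#' unknown family history) are propagated as `NA`, never imputed: the tree
#' learner routes them natively.
#'
#' Features: therapy-adjusted CombiWISE/age, measured CombiWISE, COMRIS-CTD,
#' years from disease onset to first therapy, adjusted-minus-measured
#' CombiWISE, age, family history (ordinal 0-3), sex (female = 1), race
#' (white = 1), smoking (yes = 1), number of DMT epochs shorter than 6
#' months, follow-up cumulative efficacy, and therapy type (0 none/unknown,
#' 1 low only, 2 high only, 3 both).
#'
#' @param cohort An [ms_cohort()].
#' @param anchor `"first"` or `"last"` visit anchoring.
#' @param model An [efficacy_model()].
#' @return Tibble: `patient_id`, `anchor_age`, then the columns of
#'   [msdss_feature_names()].
#' @export
build_features <- function(cohort, anchor = c("first", "last"),
                           model = efficacy_model()) {
  anchor <- match.arg(anchor)
  rv <- retained_visits(cohort) |> filter(!is.na(.data$combiwise))
  av <- if (anchor == "first") {
    slice_min(rv, .data$visit_age, n = 1, by = "patient_id", with_ties = FALSE)
  } else {
    slice_max(rv, .data$visit_age, n = 1, by = "patient_id", with_ties = FALSE)
  }
  av <- inner_join(av, cohort$demographics, by = "patient_id")
  win <- summarise(rv, t0 = min(.data$visit_age), tn = max(.data$visit_age),
                   .by = "patient_id")
  av <- left_join(av, win, by = "patient_id")
  tr_split <- split(cohort$treatments, cohort$treatments$patient_id)

  per_patient <- lapply(seq_len(nrow(av)), function(i) {
    ep <- tr_split[[av$patient_id[i]]]
    if (is.null(ep)) ep <- .empty_treatments()
    adj <- adjust_cross_sectional(av$combiwise[i], ep, av$visit_age[i], model)
    classes <- unique(ep$efficacy_class[ep$efficacy_class != "none_or_unknown"])
    tibble(
      adjusted_cw = adj$adjusted,
      onset_to_first_therapy_years =
        if (nrow(ep)) min(ep$start_age) - av$onset_age[i] else NA_real_,
      n_short_dmts = sum(ep$end_age - ep$start_age < 0.5),
      cumulative_efficacy_followup =
        if (av$tn[i] > av$t0[i]) {
          cumulative_efficacy(ep, av$t0[i], av$tn[i], model)
        } else 0,
      therapy_type = if (length(classes) == 0) 0L
        else if (setequal(classes, "low")) 1L
        else if (setequal(classes, "high")) 2L else 3L)
  }) |> purrr::list_rbind()

  tibble(
    patient_id = av$patient_id,
    anchor_age = av$visit_age,
    adj_cw_per_age = per_patient$adjusted_cw / av$visit_age,
    measured_cw = av$combiwise,
    comris_ctd = av$comris_ctd,
    onset_to_first_therapy_years = per_patient$onset_to_first_therapy_years,
    adj_minus_measured_cw = per_patient$adjusted_cw - av$combiwise,
    age = av$visit_age,
    family_history = as.numeric(family_history_ordinal(av$family_history)),
    sex = as.numeric(av$sex == "female"),
    race = as.numeric(av$race == "white"),
    smoking = as.numeric(av$smoking == "yes"),
    n_short_dmts = per_patient$n_short_dmts,
    cumulative_efficacy_followup = per_patient$cumulative_efficacy_followup,
    therapy_type = per_patient$therapy_type)
}
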