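# Builders for small in-code cohort fixtures.

demo_row <- function(patient_id, sex = "female", race = "white",
                     smoking = "yes", family_history = "none",
                     onset_age = 30) {
  tibble::tibble(patient_id = patient_id, sex = sex, race = race,
                 smoking = smoking, family_history = family_history,
                 onset_age = onset_age)
}

visit_row <- function(patient_id, visit_age, edss = 4, snrs = 70,
                      t25fw_seconds = 8, t25fw_fail = 0,
                      ndh_9hpt_seconds = 32, ndh_9hpt_fail = 0,
                      exacerbation = 0, comris_ctd = NA_real_) {
  tibble::tibble(patient_id = patient_id, visit_age = visit_age, edss = edss,
                 snrs = snrs, t25fw_seconds = t25fw_seconds,
                 t25fw_fail = t25fw_fail,
                 ndh_9hpt_seconds = ndh_9hpt_seconds,
                 ndh_9hpt_fail = ndh_9hpt_fail, exacerbation = exacerbation,
                 comris_ctd = comris_ctd)
}

epoch_row <- function(patient_id, start_age, end_age,
                      efficacy_class = "low") {
  tibble::tibble(patient_id = patient_id, start_age = start_age,
                 end_age = end_age, efficacy_class = efficacy_class)
}

empty_epochs <- function() epoch_row(character(), numeric(), numeric(),
                                     character())

# A cohort where patient `i` has visits at `ages[[i]]` with CombiWISE-bearing
# component values varied linearly so the composite moves with `values[[i]]`
# via the SNRS channel (snrs = round(100 - value) keeps everything legal).
toy_cohort <- function(ages, demo_args = list()) {
  n <- length(ages)
  ids <- sprintf("T%02d", seq_len(n))
  demo <- purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    do.call(demo_row, c(list(patient_id = ids[i]),
                        purrr::map(demo_args, i)))
  }))
  visits <- purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    visit_row(ids[i], ages[[i]])
  }))
  ms_cohort(demo, visits, empty_epochs())
}

# patients whose latent trajectory stays strictly inside the emission range:
# exact slope-recovery identities hold only off the scale floor/ceiling
interior_ids <- function(sim, lo = 1.001, hi = 94.999) {
  ok <- dplyr::summarise(sim$visit_truth,
                         inside = all(latent_cw > lo & latent_cw < hi &
                                        target_cw > lo & target_cw < hi),
                         .by = "patient_id")
  ok$patient_id[ok$inside]
}

# constant-efficacy model for exact forward/backward identities: zero age
# slope so splitting epochs is exactly invariant
flat_efficacy <- function(low_pct = 20, high_pct = 50, cap = 0.95) {
  efficacy_model(low = c(low_pct, 0), high = c(high_pct, 0), cap = cap)
}
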