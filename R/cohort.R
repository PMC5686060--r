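# Cohort container, CSV input/output, and validation of raw clinical
# measurements against their defined ranges.

fh_levels <- c("none", "mild", "moderate", "strong", "unknown")

#' Disease-modifying therapies by efficacy class
#'
#' Dichotomisation of licensed MS disease-modifying therapies into low- and
#' high-efficacy classes (from the trial meta-analysis the efficacy lines are
#' taken from). Used to map an optional `drug_name` column in treatments.csv
#' to an efficacy class; drugs not in this table are treated as zero efficacy.
#'
#' @return Tibble with columns `drug_name`, `efficacy_class`.
#' @export
dmt_efficacy_classes <- function() {
  tibble(
    drug_name = c("glatiramer acetate", "teriflunomide", "interferon beta-1a",
                  "interferon beta-1b", "peginterferon beta-1a",
                  "dimethyl fumarate", "fingolimod",
                  "natalizumab", "daclizumab", "alemtuzumab", "mitoxantrone",
                  "ocrelizumab"),
    efficacy_class = rep(c("low", "high"), c(7, 5)))
}

#' Construct a validated MS cohort
#'
#' Bundles the three cohort tables into a single validated object. Visits and
#' treatment epochs are sorted by age within patient; every measurement is
#' checked against its legal range (EDSS grid, SNRS 0-100, timed-test limits
#' of 180 s / 300 s, fail-flag consistency), treatment epochs must not
#' overlap, and disease onset must precede the first visit.
#'
#' @param demographics Data frame: `patient_id`, `sex` (`female`/`male`),
#'   `race` (`white`/`other`), `smoking` (`yes`/`no_or_unknown`),
#'   `family_history` (`none`, `mild`, `moderate`, `strong`, `unknown`, or the
#'   long questionnaire labels), `onset_age` (years).
#' @param visits Data frame: `patient_id`, `visit_age`, `edss`, `snrs`,
#'   `t25fw_seconds`, `t25fw_fail`, `ndh_9hpt_seconds`, `ndh_9hpt_fail`,
#'   `exacerbation`, `comris_ctd`.
#' @param treatments Data frame: `patient_id`, `start_age`, `end_age`, and
#'   `efficacy_class` (or `drug_name`, mapped through
#'   [dmt_efficacy_classes()]).
#' @return An object of class `ms_cohort`: a list of the three tibbles.
#' @export
ms_cohort <- function(demographics, visits, treatments) {
  demographics <- .prep_demographics(as_tibble(demographics))
  visits <- .prep_visits(as_tibble(visits))
  treatments <- .prep_treatments(as_tibble(treatments))
  x <- structure(list(demographics = demographics, visits = visits,
                      treatments = treatments),
                 class = "ms_cohort")
  validate_cohort(x)
  x
}

.require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s",
                  file, paste(missing, collapse = ", ")))
  }
}

.prep_demographics <- function(d) {
  .require_cols(d, c("patient_id", "sex", "race", "smoking",
                     "family_history", "onset_age"), "demographics")
  d$patient_id <- as.character(d$patient_id)
  d$family_history <- parse_family_history(d$family_history)
  d[c("patient_id", "sex", "race", "smoking", "family_history", "onset_age")]
}

.prep_visits <- function(v) {
  .require_cols(v, c("patient_id", "visit_age", "edss", "snrs",
                     "t25fw_seconds", "t25fw_fail", "ndh_9hpt_seconds",
                     "ndh_9hpt_fail", "exacerbation", "comris_ctd"), "visits")
  v$patient_id <- as.character(v$patient_id)
  arrange(v, .data$patient_id, .data$visit_age)
}

.prep_treatments <- function(tr) {
  .require_cols(tr, c("patient_id", "start_age", "end_age"), "treatments")
  tr$patient_id <- as.character(tr$patient_id)
  if (!"efficacy_class" %in% names(tr)) {
    if (!"drug_name" %in% names(tr)) {
      abort("treatments: need either an efficacy_class or a drug_name column.")
    }
    map <- dmt_efficacy_classes()
    cls <- map$efficacy_class[match(tolower(trimws(tr$drug_name)),
                                    map$drug_name)]
    # drugs absent from the table carry zero (unknown) efficacy
    tr$efficacy_class <- ifelse(is.na(cls), "none_or_unknown", cls)
  }
  arrange(tr, .data$patient_id, .data$start_age)
}

#' Parse family-history labels to the canonical ordered categories
#'
#' Accepts the short canonical labels (`none`, `mild`, `moderate`, `strong`,
#' `unknown`) or the long questionnaire labels such as
#' `"Strong (first degree relative with definite MS)"`.
#'
#' @param x Character vector of labels.
#' @return Character vector on the canonical levels.
#' @export
parse_family_history <- function(x) {
  key <- tolower(trimws(sub("\\s*\\(.*$", "", as.character(x))))
  out <- dplyr::case_match(key,
    c("none", "no") ~ "none",
    "mild" ~ "mild",
    "moderate" ~ "moderate",
    "strong" ~ "strong",
    "unknown" ~ "unknown",
    .default = NA_character_)
  if (any(is.na(out) & !is.na(x))) {
    abort(sprintf("unrecognised family_history label: '%s'",
                  x[which(is.na(out) & !is.na(x))[1]]))
  }
  out
}

#' Family history as an ordinal score
#'
#' `none` = 0, `mild` = 1, `moderate` = 2, `strong` = 3; `unknown` is
#' propagated as `NA`.
#'
#' @param x Character vector on the canonical family-history levels.
#' @return Integer vector (with `NA` for unknown).
#' @export
family_history_ordinal <- function(x) {
  m <- c(none = 0L, mild = 1L, moderate = 2L, strong = 3L)
  unname(m[as.character(x)])
}

#' Validate an `ms_cohort`
#'
#' Applies every field-level range rule and the structural invariants
#' (strictly increasing visit ages, non-overlapping treatment epochs,
#' onset before first visit). Called by [ms_cohort()] and [read_cohort()];
#' exported so externally assembled objects can be re-checked.
#'
#' @param x An `ms_cohort`.
#' @return `x`, invisibly; aborts with a message naming patient and field on
#'   the first violation.
#' @export
validate_cohort <- function(x) {
  d <- x$demographics; v <- x$visits; tr <- x$treatments
  if (anyDuplicated(d$patient_id)) abort("demographics: duplicated patient_id.")
  .check_levels(d$sex, c("female", "male"), "sex")
  .check_levels(d$race, c("white", "other"), "race")
  .check_levels(d$smoking, c("yes", "no_or_unknown"), "smoking")
  .check_levels(d$family_history, fh_levels, "family_history")
  if (any(is.na(d$onset_age) | d$onset_age < 0)) {
    abort("demographics: onset_age must be a nonnegative age in years.")
  }
  orphan <- setdiff(unique(c(v$patient_id, tr$patient_id)), d$patient_id)
  if (length(orphan)) {
    abort(sprintf("patient_id '%s' appears in visits/treatments but not demographics.",
                  orphan[1]))
  }

  .validate_visit_fields(v)
  .validate_treatment_fields(tr)

  # per-patient structural rules
  dup <- v |> summarise(dup = anyDuplicated(.data$visit_age) > 0,
                        .by = "patient_id")
  if (any(dup$dup)) {
    abort(sprintf("patient %s: visit ages must be strictly increasing.",
                  dup$patient_id[dup$dup][1]))
  }
  if (nrow(v)) {
    first_v <- v |> summarise(first_age = min(.data$visit_age),
                              .by = "patient_id")
    j <- inner_join(first_v, d, by = "patient_id")
    bad <- j$onset_age > j$first_age + 1e-9
    if (any(bad)) {
      abort(sprintf("patient %s: onset_age exceeds first visit_age.",
                    j$patient_id[bad][1]))
    }
  }
  if (nrow(tr)) {
    ov <- tr |>
      arrange(.data$patient_id, .data$start_age) |>
      mutate(overlap = .data$start_age < lag(.data$end_age, default = -Inf) - 1e-9,
             .by = "patient_id")
    if (any(ov$overlap)) {
      abort(sprintf("patient %s: overlapping treatment epochs.",
                    ov$patient_id[ov$overlap][1]))
    }
  }
  invisible(x)
}

.check_levels <- function(x, levels, field) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    abort(sprintf("%s: illegal value '%s' (allowed: %s)", field, x[bad][1],
                  paste(levels, collapse = ", ")))
  }
}

.validate_visit_fields <- function(v) {
  .row_check(v, !is.na(v$visit_age) & v$visit_age > 0,
             "visit_age must be a positive age in years")
  .row_check(v, is.na(v$edss) | is_edss(v$edss),
             "edss is not on the legal grid (0, 1-10 by 0.5)")
  .row_check(v, is.na(v$snrs) | (v$snrs >= 0 & v$snrs <= 100),
             "snrs outside [0, 100]")
  .row_check(v, is.na(v$t25fw_seconds) |
               (v$t25fw_seconds > 0 &
                  v$t25fw_seconds <= cw_time_limits[["t25fw"]]),
             sprintf("t25fw_seconds outside (0, %g]; times above the limit are failed tests",
                     cw_time_limits[["t25fw"]]))
  .row_check(v, is.na(v$ndh_9hpt_seconds) |
               (v$ndh_9hpt_seconds > 0 &
                  v$ndh_9hpt_seconds <= cw_time_limits[["ndh_9hpt"]]),
             sprintf("ndh_9hpt_seconds outside (0, %g]; times above the limit are failed tests",
                     cw_time_limits[["ndh_9hpt"]]))
  .row_check(v, v$t25fw_fail %in% c(0, 1) & v$ndh_9hpt_fail %in% c(0, 1) &
               v$exacerbation %in% c(0, 1),
             "fail/exacerbation flags must be 0 or 1")
  .row_check(v, !(v$t25fw_fail == 1 & !is.na(v$t25fw_seconds)),
             "t25fw time recorded together with fail flag 1")
  .row_check(v, !(v$ndh_9hpt_fail == 1 & !is.na(v$ndh_9hpt_seconds)),
             "ndh_9hpt time recorded together with fail flag 1")
  .row_check(v, is.na(v$comris_ctd) | v$comris_ctd >= 0,
             "comris_ctd must be nonnegative")
}

.validate_treatment_fields <- function(tr) {
  if (!nrow(tr)) return(invisible(TRUE))
  .row_check(tr, !is.na(tr$start_age) & tr$start_age >= 0,
             "start_age must be nonnegative")
  .row_check(tr, !is.na(tr$end_age) & tr$end_age > tr$start_age,
             "end_age must exceed start_age")
  .check_levels(tr$efficacy_class, efficacy_classes, "efficacy_class")
}

.row_check <- function(df, ok, msg) {
  ok[is.na(ok)] <- FALSE
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("patient %s, row %d: %s.", df$patient_id[i], i, msg))
  }
  invisible(TRUE)
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d patients, %d visits, %d treatment epochs\n",
              nrow(x$demographics), nrow(x$visits), nrow(x$treatments)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x An `ms_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(x) nrow(x$demographics)

#' Read a cohort from its three CSV files
#'
#' Reads `demographics.csv`, `visits.csv` and `treatments.csv` (UTF-8, header
#' row, `.` decimal point), attaches visits and epochs to patients, and
#' validates every field. If the files carry calendar dates
#' (`visit_date`/`start_date`/`end_date` plus a `birthdate` column in
#' demographics, ISO `YYYY-MM-DD`), they are converted to decimal ages as
#' `(date - birthdate) / 365.25` at read time; all downstream computation is
#' on the age axis.
#'
#' @param dir Directory containing the three files, or `NULL` if explicit
#'   paths are given.
#' @param demographics,visits,treatments Explicit file paths (default:
#'   `<dir>/<name>.csv`).
#' @return A validated [ms_cohort()].
#' @export
read_cohort <- function(dir = NULL,
                        demographics = file.path(dir, "demographics.csv"),
                        visits = file.path(dir, "visits.csv"),
                        treatments = file.path(dir, "treatments.csv")) {
  d <- .read_csv(demographics)
  v <- .read_csv(visits)
  tr <- .read_csv(treatments)
  if ("birthdate" %in% names(d)) {
    bd <- as.Date(d$birthdate)
    names(bd) <- as.character(d$patient_id)
    if ("visit_date" %in% names(v) && !"visit_age" %in% names(v)) {
      v$visit_age <- .date_to_age(v$visit_date, bd[as.character(v$patient_id)])
    }
    if (nrow(tr) && "start_date" %in% names(tr) && !"start_age" %in% names(tr)) {
      tr$start_age <- .date_to_age(tr$start_date, bd[as.character(tr$patient_id)])
      tr$end_age <- .date_to_age(tr$end_date, bd[as.character(tr$patient_id)])
    }
    d$birthdate <- NULL
  }
  if (nrow(v) == 0) v <- .empty_visits()
  if (nrow(tr) == 0) tr <- .empty_treatments()
  ms_cohort(d, v, tr)
}

.date_to_age <- function(date, birthdate) {
  as.numeric(as.Date(date) - birthdate) / 365.25
}

.read_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

.empty_visits <- function() {
  tibble(patient_id = character(), visit_age = numeric(), edss = numeric(),
         snrs = numeric(), t25fw_seconds = numeric(), t25fw_fail = numeric(),
         ndh_9hpt_seconds = numeric(), ndh_9hpt_fail = numeric(),
         exacerbation = numeric(), comris_ctd = numeric())
}

.empty_treatments <- function() {
  tibble(patient_id = character(), start_age = numeric(), end_age = numeric(),
         efficacy_class = character())
}

#' Write a cohort to CSV files
#'
#' Emits `demographics.csv`, `visits.csv` and `treatments.csv` such that
#' [read_cohort()] on the output reproduces the cohort field for field.
#'
#' @param cohort An `ms_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$treatments, file.path(dir, "treatments.csv"),
                   progress = FALSE)
  invisible(dir)
}
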