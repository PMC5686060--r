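# Local-reference rank severity scores: MSSS conditions EDSS rank on disease
# duration, ARMSS conditions it on age. Built from the supplied cohort by
# default; a user-supplied reference in the same format is accepted for those
# who have the published global tables.

#' Build a rank-severity reference distribution
#'
#' Bins the first-visit EDSS of every patient by the chosen conditioning
#' variable (disease duration for MSSS, age for ARMSS). Bins holding fewer
#' than `min_count` patients are merged outward into their neighbours, so
#' every usable bin supports a stable rank.
#'
#' @param cohort An [ms_cohort()], or a data frame with columns `key`
#'   (conditioning value in years) and `edss`.
#' @param conditioning `"disease_duration"` or `"age"`.
#' @param bin_width Bin width in years; defaults to 1 for disease duration
#'   (the per-year convention of duration-conditioned severity scores) and 5
#'   for age.
#' @param min_count Minimum patients per usable bin (default 5).
#' @return An object of class `severity_reference`.
#' @export
build_reference <- function(cohort,
                            conditioning = c("disease_duration", "age"),
                            bin_width = NULL, min_count = 5) {
  conditioning <- match.arg(conditioning)
  bin_width <- bin_width %||% if (conditioning == "disease_duration") 1 else 5
  df <- if (inherits(cohort, "ms_cohort")) {
    fv <- first_visits(cohort)
    tibble(key = if (conditioning == "disease_duration") {
      fv$visit_age - fv$onset_age
    } else fv$visit_age,
    edss = fv$edss)
  } else {
    as_tibble(cohort)[c("key", "edss")]
  }
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) == 0) abort("cannot build a reference from an empty cohort.")

  lo <- floor(min(df$key) / bin_width) * bin_width
  hi <- max(df$key)
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  idx <- findInterval(df$key, breaks, rightmost.closed = TRUE)
  values <- split(df$edss, factor(idx, levels = seq_len(length(breaks) - 1)))

  # merge sparse bins outward into their nearest neighbour until all usable
  bins <- tibble(lower = head(breaks, -1), upper = tail(breaks, -1),
                 values = unname(values)) |>
    mutate(n = lengths(.data$values)) |>
    filter(.data$n > 0)
  while (nrow(bins) > 1 && any(bins$n < min_count)) {
    i <- which.min(bins$n)
    j <- if (i == 1) 2 else if (i == nrow(bins)) i - 1 else {
      if (bins$n[i - 1] <= bins$n[i + 1]) i - 1 else i + 1
    }
    a <- min(i, j); b <- max(i, j)
    bins$values[[a]] <- c(bins$values[[a]], bins$values[[b]])
    bins$upper[a] <- bins$upper[b]
    bins$n[a] <- bins$n[a] + bins$n[b]
    bins <- bins[-b, ]
  }
  structure(list(conditioning = conditioning, bin_width = bin_width,
                 min_count = min_count, bins = bins),
            class = "severity_reference")
}

#' @export
print.severity_reference <- function(x, ...) {
  cat(sprintf("<severity_reference> conditioned on %s, %d bin(s), %d patients\n",
              x$conditioning, nrow(x$bins), sum(x$bins$n)))
  invisible(x)
}

#' Rank an EDSS score within its reference bin
#'
#' Severity is the tied-rank position of the EDSS score within the reference
#' bin covering `key`, scaled to the open interval (0, 10):
#' `10 * rank / (N + 1)`, where `rank` is the average tied rank of the score
#' in the bin's multiset (the scored value is included if not already a bin
#' member) and `N` is that multiset's size. Conditioning on disease duration
#' yields MSSS; conditioning on age yields ARMSS.
#'
#' @param edss EDSS score(s) on the legal grid (vectorised).
#' @param key Conditioning value(s) in years (disease duration or age).
#' @param ref A [build_reference()] object.
#' @return Severity score(s) strictly inside (0, 10).
#' @examples
#' ref <- build_reference(tibble::tibble(key = rep(2, 9), edss = 1:9),
#'                        "disease_duration")
#' compute_rank_severity(5, 2, ref)  # 5.0
#' @export
compute_rank_severity <- function(edss, key, ref) {
  stopifnot(inherits(ref, "severity_reference"))
  n <- max(length(edss), length(key))
  edss <- rep_len(edss, n); key <- rep_len(key, n)
  bins <- ref$bins
  vapply(seq_len(n), function(i) {
    if (is.na(edss[i]) || is.na(key[i])) return(NA_real_)
    b <- which(key[i] >= bins$lower & key[i] <= bins$upper)
    if (!length(b)) {
      # keys beyond the covered range fall into the nearest edge bin
      b <- if (key[i] < bins$lower[1]) 1L else nrow(bins)
    }
    b <- b[1]
    ms <- bins$values[[b]]
    if (!any(abs(ms - edss[i]) < 1e-9)) ms <- c(ms, edss[i])
    r <- mean(rank(ms)[abs(ms - edss[i]) < 1e-9])
    10 * r / (length(ms) + 1)
  }, numeric(1))
}

#' First analysable visit per patient
#'
#' The first non-exacerbation visit (exacerbation visits overestimate
#' sustained disability and are excluded throughout), joined to demographics.
#' With `which = "last"` returns the last such visit instead.
#'
#' @param cohort An [ms_cohort()].
#' @param which `"first"` or `"last"`.
#' @return Tibble: one row per patient with the visit fields and demographics.
#' @export
first_visits <- function(cohort, which = c("first", "last")) {
  which <- match.arg(which)
  v <- filter(cohort$visits, .data$exacerbation == 0)
  v <- if (which == "first") {
    slice_min(v, .data$visit_age, n = 1, by = "patient_id", with_ties = FALSE)
  } else {
    slice_max(v, .data$visit_age, n = 1, by = "patient_id", with_ties = FALSE)
  }
  inner_join(v, cohort$demographics, by = "patient_id")
}

#' Score a cohort on all cross-sectional severity scales
#'
#' For every patient's anchor visit (first non-exacerbation visit by default)
#' computes CombiWISE, CombiWISE/age, and local-reference MSSS and ARMSS, and
#' returns them in long form, one row per patient and scale.
#'
#' @param cohort An [ms_cohort()].
#' @param anchor `"first"` or `"last"` visit.
#' @param msss_ref,armss_ref Optional pre-built [build_reference()] objects
#'   (e.g. from an external reference population); built from the cohort when
#'   `NULL`.
#' @return Tibble: `patient_id`, `visit_age`, `scale_name`
#'   (`CombiWISE`, `CW_per_age`, `MSSS`, `ARMSS`), `value`.
#' @export
score_cohort <- function(cohort, anchor = c("first", "last"),
                         msss_ref = NULL, armss_ref = NULL) {
  anchor <- match.arg(anchor)
  fv <- first_visits(cohort, which = anchor)
  cw <- compute_combiwise(fv$edss, fv$snrs, fv$t25fw_seconds, fv$t25fw_fail,
                          fv$ndh_9hpt_seconds, fv$ndh_9hpt_fail)
  msss_ref <- msss_ref %||% build_reference(cohort, "disease_duration")
  armss_ref <- armss_ref %||% build_reference(cohort, "age")
  msss <- compute_rank_severity(fv$edss, fv$visit_age - fv$onset_age, msss_ref)
  armss <- compute_rank_severity(fv$edss, fv$visit_age, armss_ref)
  tibble(patient_id = rep(fv$patient_id, 4),
         visit_age = rep(fv$visit_age, 4),
         scale_name = rep(c("CombiWISE", "CW_per_age", "MSSS", "ARMSS"),
                          each = nrow(fv)),
         value = c(cw, compute_cw_per_age(cw, fv$visit_age), msss, armss))
}
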