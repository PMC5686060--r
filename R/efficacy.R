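# Therapy-efficacy calculus: age-dependent per-epoch efficacy, duration-
# weighted cumulative efficacy, and adjustment of slopes and cross-sectional
# disability toward their untreated equivalents.

#' Age-dependent therapy-efficacy model
#'
#' Disease-modifying therapies are dichotomised into low- and high-efficacy
#' classes; within each class, the percentage inhibition of disability
#' progression declines linearly with the patient's age (coefficients from a
#' meta-analysis of randomised trials, taken as given constants):
#' low-efficacy \eqn{-1.50\,\bar a + 83.71} percent,
#' high-efficacy \eqn{-4.34\,\bar a + 206.39} percent, where \eqn{\bar a} is
#' the mean age over the treatment epoch. Untreated or unknown epochs have
#' zero efficacy. Negative evaluated efficacies are floored at 0; the
#' high-efficacy line exceeds 100% at young ages, so raw per-epoch fractions
#' are capped (default 0.95) to keep the downstream `1 - Eff` adjustments
#' finite.
#'
#' @param low,high Numeric `c(intercept, age_slope)` of the percent-efficacy
#'   line for each class.
#' @param cap Upper bound (fraction, < 1) applied to each epoch's efficacy.
#' @return An object of class `efficacy_model`.
#' @examples
#' m <- efficacy_model()
#' epoch_efficacy(39, 41, "high", m)
#' @export
efficacy_model <- function(low = c(intercept = 83.71, age_slope = -1.50),
                           high = c(intercept = 206.39, age_slope = -4.34),
                           cap = 0.95) {
  stopifnot(length(low) == 2, length(high) == 2, cap > 0, cap < 1)
  structure(
    list(coefficients = list(
           none_or_unknown = c(intercept = 0, age_slope = 0),
           low = setNames(as.numeric(low), c("intercept", "age_slope")),
           high = setNames(as.numeric(high), c("intercept", "age_slope"))),
         cap = cap),
    class = "efficacy_model")
}

#' @export
print.efficacy_model <- function(x, ...) {
  cat("<efficacy_model>\n")
  for (cl in c("low", "high")) {
    co <- x$coefficients[[cl]]
    cat(sprintf("  %-4s: Eff = %.2f %+.2f * mean_age  (percent)\n",
                cl, co[["intercept"]], co[["age_slope"]]))
  }
  cat(sprintf("  floor 0, cap %.2f (fractions)\n", x$cap))
  invisible(x)
}

efficacy_classes <- c("none_or_unknown", "low", "high")

#' Per-epoch therapeutic efficacy
#'
#' Evaluates the class efficacy line at the epoch's mean age
#' `(start_age + end_age) / 2`, converts percent to a fraction, and clamps to
#' `[0, cap]`.
#'
#' @param start_age,end_age Epoch bounds in decimal years (vectorised).
#' @param efficacy_class `"none_or_unknown"`, `"low"`, or `"high"`.
#' @param model An [efficacy_model()].
#' @return Efficacy fraction(s) in `[0, cap]`.
#' @export
epoch_efficacy <- function(start_age, end_age, efficacy_class,
                           model = efficacy_model()) {
  n <- max(length(start_age), length(end_age), length(efficacy_class))
  start_age <- rep_len(start_age, n); end_age <- rep_len(end_age, n)
  efficacy_class <- rep_len(as.character(efficacy_class), n)
  if (!all(efficacy_class %in% efficacy_classes)) {
    abort(sprintf("unknown efficacy class: %s",
                  setdiff(efficacy_class, efficacy_classes)[1]))
  }
  if (any(end_age <= start_age)) abort("epoch end_age must exceed start_age.")
  mean_age <- (start_age + end_age) / 2
  co <- model$coefficients
  pct <- vapply(seq_len(n), function(i) {
    cf <- co[[efficacy_class[i]]]
    cf[["intercept"]] + cf[["age_slope"]] * mean_age[i]
  }, numeric(1))
  pmin(pmax(pct / 100, 0), model$cap)
}

#' Duration-weighted cumulative therapeutic efficacy over a window
#'
#' The cumulative efficacy over `[t0, tn]` is the duration-weighted average of
#' per-epoch efficacies, with untreated gaps contributing zero:
#' \deqn{\mathrm{Eff}(t_0,t_n) = \sum_i (t_i - t_{i-1})\,\mathrm{Eff}_i / (t_n - t_0).}
#' Epochs extending beyond the window are clipped to it before mean-age
#' evaluation.
#'
#' @param epochs Data frame of treatment epochs with columns `start_age`,
#'   `end_age`, `efficacy_class` (may have zero rows = never treated).
#' @param t0,tn Window bounds in decimal years, `tn > t0`.
#' @param model An [efficacy_model()].
#' @return Cumulative efficacy fraction in `[0, cap]`.
#' @export
cumulative_efficacy <- function(epochs, t0, tn, model = efficacy_model()) {
  if (!is.numeric(t0) || !is.numeric(tn) || tn <= t0) {
    abort("cumulative_efficacy requires tn > t0.")
  }
  if (is.null(epochs) || nrow(epochs) == 0) return(0)
  s <- pmax(epochs$start_age, t0)
  e <- pmin(epochs$end_age, tn)
  keep <- e > s
  if (!any(keep)) return(0)
  eff <- epoch_efficacy(s[keep], e[keep], epochs$efficacy_class[keep], model)
  sum((e[keep] - s[keep]) * eff) / (tn - t0)
}

#' Adjust a measured progression slope for therapy received during follow-up
#'
#' Recovers the progression slope the patient would have shown untreated. For
#' a progressing patient (positive measured slope) therapy masks a fraction
#' `eff` of the untreated slope, so `adjusted = measured / (1 - eff)`; for an
#' improving patient (negative slope) the untreated rate of improvement is
#' slower, `adjusted = measured * (1 - eff)`. A zero slope is unchanged (both
#' branches agree in the limit). The adjusted slope is never below the
#' measured one.
#'
#' @param measured Measured slope(s), CombiWISE units per year (vectorised).
#' @param eff Cumulative efficacy fraction(s) in `[0, 1)`.
#' @return Adjusted slope(s), same units.
#' @examples
#' adjust_slope(1.0, 0.25)   # 1.333...
#' adjust_slope(-1.0, 0.25)  # -0.75
#' @export
adjust_slope <- function(measured, eff) {
  if (any(!is.na(eff) & (eff < 0 | eff >= 1))) {
    abort("cumulative efficacy must lie in [0, 1).")
  }
  ifelse(measured > 0, measured / (1 - eff),
         ifelse(measured < 0, measured * (1 - eff), measured))
}

#' Adjust a cross-sectional CombiWISE score for all past therapy
#'
#' Shifts a measured disability score upward to its untreated equivalent,
#' `cw / (1 - Eff(0, visit_age))`, where the cumulative efficacy window runs
#' from birth to the visit (disease onset cannot be timed precisely, so the
#' window is birth-anchored).
#'
#' @param cw Measured CombiWISE score (>= 0).
#' @param epochs Treatment epochs data frame (see [cumulative_efficacy()]);
#'   epochs after `visit_age` are clipped away.
#' @param visit_age Age at the cross-sectional visit, years (> 0).
#' @param model An [efficacy_model()].
#' @return A tibble with columns `measured`, `efficacy_used`, `adjusted`.
#' @export
adjust_cross_sectional <- function(cw, epochs, visit_age,
                                   model = efficacy_model()) {
  if (any(!is.na(cw) & cw < 0)) abort("cw must be nonnegative.")
  if (visit_age <= 0) abort("visit_age must be positive.")
  eff <- cumulative_efficacy(epochs, 0, visit_age, model)
  tibble(measured = cw, efficacy_used = eff, adjusted = cw / (1 - eff))
}
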