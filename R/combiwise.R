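# CombiWISE composite disability score and derived per-age severity.

# Published regression weights of the composite (intercept, EDSS, SNRS,
# log2 walk time, walk failure, log2 peg time, peg failure).
.cw_coef <- c(
  intercept = 33.166,
  edss      = 3.803,
  snrs      = -0.407,
  log2_t25  = 2.409,
  t25_fail  = 18.056,
  log2_hpt  = 1.305,
  hpt_fail  = 10.751
)

#' Maximum permitted times for the timed component tests (seconds)
#'
#' Trials exceeding these limits are recorded as failed tests; times above the
#' limit are invalid input.
#' @format Named numeric vector with elements `t25fw` (180 s) and
#'   `ndh_9hpt` (300 s).
#' @export
cw_time_limits <- c(t25fw = 180, ndh_9hpt = 300)

#' Legal EDSS grid
#'
#' EDSS takes the value 0 or any half-step from 1.0 to 10.0.
#' @return Numeric vector of legal EDSS values.
#' @export
edss_grid <- function() c(0, seq(1, 10, by = 0.5))

is_edss <- function(x) {
  !is.na(x) & vapply(x, function(v) any(abs(v - edss_grid()) < 1e-9), logical(1))
}

#' Compute the CombiWISE composite disability score
#'
#' CombiWISE combines EDSS, SNRS, the Timed 25-Foot Walk (T25FW) and the
#' non-dominant-hand 9-Hole Peg Test (9HPT) into a continuous 0-100
#' disability score:
#' \deqn{33.166 + 3.803\,\mathrm{EDSS} - 0.407\,\mathrm{SNRS}
#'   + 2.409\log_2(\mathrm{T25FW}) + 18.056\,\mathrm{T25FW_{fail}}
#'   + 1.305\log_2(\mathrm{9HPT}) + 10.751\,\mathrm{9HPT_{fail}}}
#'
#' A failed timed test (time limit exceeded: 180 s for T25FW, 300 s for the
#' 9HPT) is encoded by its fail flag; the log term is then evaluated at the
#' test ceiling and the fail bonus added, which keeps the score continuous at
#' the pass/fail boundary. A recorded time together with a raised fail flag is
#' inconsistent and rejected. The result is clipped to the scale's 0-100
#' range.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param edss EDSS score: 0 or 1.0-10.0 in steps of 0.5.
#' @param snrs Scripps Neurological Rating Scale, integer 0-100.
#' @param t25fw T25FW time in seconds (0 < t <= 180), or `NA` if failed.
#' @param t25fw_fail 0/1 flag: 1 if the walk test was failed.
#' @param ndh_9hpt Non-dominant-hand 9HPT time in seconds (0 < t <= 300), or
#'   `NA` if failed.
#' @param ndh_9hpt_fail 0/1 flag: 1 if the peg test was failed.
#' @param clip Clip the result to \[0, 100\] (default `TRUE`).
#' @return Numeric vector of CombiWISE scores. Elements where `edss` or `snrs`
#'   is missing, or where a timed test has neither a time nor a fail flag, are
#'   `NA`.
#' @examples
#' compute_combiwise(edss = 4, snrs = 70, t25fw = 8, ndh_9hpt = 32)
#' @export
compute_combiwise <- function(edss, snrs, t25fw = NA_real_, t25fw_fail = 0,
                              ndh_9hpt = NA_real_, ndh_9hpt_fail = 0,
                              clip = TRUE) {
  n <- max(length(edss), length(snrs), length(t25fw), length(t25fw_fail),
           length(ndh_9hpt), length(ndh_9hpt_fail))
  edss <- rep_len(edss, n); snrs <- rep_len(snrs, n)
  t25fw <- rep_len(as.numeric(t25fw), n); t25fw_fail <- rep_len(t25fw_fail, n)
  ndh_9hpt <- rep_len(as.numeric(ndh_9hpt), n)
  ndh_9hpt_fail <- rep_len(ndh_9hpt_fail, n)

  bad_edss <- !is.na(edss) & !is_edss(edss)
  if (any(bad_edss)) {
    abort(sprintf("EDSS value %s is not on the legal grid (0, 1-10 by 0.5).",
                  edss[which(bad_edss)[1]]))
  }
  if (any(!is.na(snrs) & (snrs < 0 | snrs > 100))) {
    abort("SNRS must lie in [0, 100].")
  }
  .check_timed(t25fw, t25fw_fail, cw_time_limits[["t25fw"]], "t25fw")
  .check_timed(ndh_9hpt, ndh_9hpt_fail, cw_time_limits[["ndh_9hpt"]], "ndh_9hpt")

  lt25 <- .log2_timed(t25fw, t25fw_fail, cw_time_limits[["t25fw"]])
  lhpt <- .log2_timed(ndh_9hpt, ndh_9hpt_fail, cw_time_limits[["ndh_9hpt"]])

  out <- .cw_coef[["intercept"]] +
    .cw_coef[["edss"]] * edss +
    .cw_coef[["snrs"]] * snrs +
    .cw_coef[["log2_t25"]] * lt25 +
    .cw_coef[["t25_fail"]] * as.numeric(t25fw_fail > 0) +
    .cw_coef[["log2_hpt"]] * lhpt +
    .cw_coef[["hpt_fail"]] * as.numeric(ndh_9hpt_fail > 0)
  if (clip) out <- pmin(pmax(out, 0), 100)
  unname(out)
}

.check_timed <- function(time, fail, limit, name) {
  fail <- !is.na(fail) & fail > 0
  if (any(!is.na(time) & fail)) {
    abort(sprintf(
      "%s: a recorded time together with fail flag 1 is inconsistent; failed tests carry no time.",
      name))
  }
  if (any(!is.na(time) & time <= 0)) {
    abort(sprintf("%s: times must be positive seconds.", name))
  }
  if (any(!is.na(time) & time > limit)) {
    abort(sprintf("%s: time exceeds the %g s test limit; record the test as failed instead.",
                  name, limit))
  }
  invisible(TRUE)
}

# log2 of a timed test; failed tests are evaluated at the test ceiling
# (fail bonus is added separately). NA when neither time nor fail is given.
.log2_timed <- function(time, fail, limit) {
  fail <- !is.na(fail) & fail > 0
  out <- ifelse(fail, log2(limit), log2(time))
  out
}

#' CombiWISE per year of age
#'
#' Cross-sectional disability divided by age, the continuous-scale analogue of
#' age-conditioned severity ranking.
#'
#' @param cw CombiWISE score (0-100).
#' @param age Age in decimal years; must be positive.
#' @return `cw / age`, score per year.
#' @examples
#' compute_cw_per_age(30, 50)
#' @export
compute_cw_per_age <- function(cw, age) {
  if (any(!is.na(age) & age <= 0)) abort("age must be positive.")
  cw / age
}
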