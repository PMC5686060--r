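# Stratified 2:1 partitioning and random-partition stability.

fake_features <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    race = sample(c("white", "other"), n, TRUE, prob = c(0.85, 0.15)),
    sex = sample(c("female", "male"), n, TRUE),
    adj_cw_per_age = runif(n, 0.1, 2),
    age = runif(n, 23, 70))
}

test_that("cell-level rounding follows the 2:1 round-half-up rule", {
  f <- fake_features(12)
  f$race <- "white"; f$sex <- "female"
  f$adj_cw_per_age <- 1; f$age <- 40   # single cell of 12
  sp <- stratified_split(f, seed = 3)
  expect_equal(sum(sp$arm == "train"), 8)
  expect_equal(sum(sp$arm == "validation"), 4)
  one <- stratified_split(f[1, ], seed = 3)
  expect_equal(one$arm, "train")   # 2/3 of 1 rounds up to 1
  expect_error(stratified_split(f[0, ], seed = 3), "empty")
})

test_that("arms are disjoint and exhaustive with per-cell 2:1 within one patient", {
  f <- fake_features(201)
  for (seed in c(1, 17, 99)) {
    sp <- stratified_split(f, seed = seed)
    expect_setequal(sp$patient_id, f$patient_id)
    expect_equal(anyDuplicated(sp$patient_id), 0)
    per_cell <- dplyr::summarise(sp, n = dplyr::n(),
                                 n_train = sum(arm == "train"),
                                 .by = "cell_id")
    expect_true(all(abs(per_cell$n_train - 2 * per_cell$n / 3) <= 0.5 + 1e-9))
  }
  # overall arm sizes near the 2:1 target for a 201-patient cohort
  sp <- stratified_split(f, seed = 1)
  expect_lte(abs(sum(sp$arm == "train") - 134), 3)
  expect_lte(abs(sum(sp$arm == "validation") - 67), 3)
})

test_that("median dichotomisation sends ties to the lower bin and is configurable", {
  f <- fake_features(9)
  f$adj_cw_per_age <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)  # median 2
  sp_lower <- stratified_split(f, seed = 1, ties = "lower")
  sp_upper <- stratified_split(f, seed = 1, ties = "upper")
  bin_of <- function(sp) vapply(strsplit(sp$cell_id, "/"), `[`, "", 3)
  at_median <- f$adj_cw_per_age == 2
  expect_true(all(bin_of(sp_lower)[match(f$patient_id[at_median],
                                         sp_lower$patient_id)] == "low"))
  expect_true(all(bin_of(sp_upper)[match(f$patient_id[at_median],
                                         sp_upper$patient_id)] == "high"))
})

test_that("splits are deterministic in the seed and stratification balances arms", {
  f <- fake_features(180, seed = 4)
  expect_identical(stratified_split(f, seed = 5), stratified_split(f, seed = 5))
  expect_false(identical(stratified_split(f, seed = 5)$arm,
                         stratified_split(f, seed = 6)$arm))

  # balance: mean absolute standardised arm difference of the stratification
  # variables, averaged over seeds, should not exceed fully random splitting
  imbalance <- function(arm) {
    vars <- cbind(as.numeric(f$race == "white"),
                  as.numeric(f$sex == "female"),
                  f$adj_cw_per_age, f$age)
    mean(abs(colMeans(vars[arm == "train", , drop = FALSE]) -
               colMeans(vars[arm == "validation", , drop = FALSE])) /
           apply(vars, 2, sd))
  }
  seeds <- 1:60
  strat <- vapply(seeds, function(s)
    imbalance(stratified_split(f, seed = s)$arm), numeric(1))
  rand <- vapply(seeds, function(s) {
    set.seed(s + 1000)
    arm <- rep("validation", nrow(f))
    arm[sample.int(nrow(f), floor(2 * nrow(f) / 3 + 0.5))] <- "train"
    imbalance(arm)
  }, numeric(1))
  expect_lt(mean(strat), mean(rand))
})

test_that("partition stability returns a deterministic correlation distribution", {
  f <- fake_features(90, seed = 2)
  y <- f$adj_cw_per_age + rnorm(90, 0, 0.3)
  # a plain lm fit is a valid trainer result: predict() dispatches on it
  lm_trainer <- function(feats, target, seed) {
    lm(target ~ adj_cw_per_age, data = cbind(feats, target = target))
  }
  st1 <- partition_stability(f, y, n_partitions = 20, seed = 7,
                             trainer = lm_trainer)
  st2 <- partition_stability(f, y, n_partitions = 20, seed = 7,
                             trainer = lm_trainer)
  expect_identical(st1$correlations, st2$correlations)
  expect_gt(st1$summary$sd, 0)
  expect_gt(st1$summary$mean, 0.5)
  expect_equal(st1$summary$n_dropped, 0)

  # constant predictor: degenerate distribution handled as zero correlation
  const_trainer <- function(feats, target, seed) {
    lm(target ~ 1, data = data.frame(target = target))
  }
  st3 <- partition_stability(f, y, n_partitions = 2, seed = 7,
                             trainer = const_trainer)
  expect_equal(st3$correlations, c(0, 0))
})
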