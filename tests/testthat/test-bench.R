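# Classification bench: scaling, labelling, grid search, determinism.

test_that("min-max scaling maps training columns onto [0, 1]", {
  out <- scaleMinMax(data.frame(a = c(2, 4, 6)))
  expect_equal(unname(out$scaled[, "a"]), c(0, 0.5, 1))
  # constant column scales to 0 with a warning
  expect_warning(cc <- scaleMinMax(data.frame(a = c(3, 3, 3))), "constant")
  expect_equal(unname(cc$scaled[, "a"]), c(0, 0, 0))
  # held-out values outside the training range pass through unclipped
  tr <- scaleMinMax(data.frame(a = c(2, 4, 6)))
  held <- scaleMinMax(data.frame(a = 8), tr$ranges)
  expect_equal(unname(held$scaled[, "a"]), 1.5)
})

test_that("task labelling merges, restricts and excludes as specified", {
  meta <- data.frame(
    group = c("PD", "PD", "EL", "S", "PD"),
    medication_state = c("ON", "OFF", NA, NA, "DCIP"),
    severity_level = c("mild", "moderate", NA, NA, "moderate"),
    stringsAsFactors = FALSE)
  lab <- makeLabels(meta, "PD_NONPD")
  expect_equal(as.character(lab), c("PD", "PD", "nonPD", "nonPD", "PD"))
  lab <- makeLabels(meta, "ON_OFF")
  expect_equal(as.character(lab), c("ON", "OFF", NA, NA, NA))
  expect_equal(attr(lab, "excluded"), 3L)   # controls and DCIP dropped
  lab <- makeLabels(meta, "SEVERITY")
  expect_equal(as.character(lab), c("mild", "moderate", NA, NA, "moderate"))
  # severity from raw Part III totals when no level column is present
  meta2 <- data.frame(group = "PD", medication_state = "ON",
                      part3_total = 42)
  expect_equal(as.character(makeLabels(meta2, "SEVERITY")), "moderate")
})

test_that("a linearly separable table is classified perfectly", {
  tab <- simulateFeatureTable(c(S = 15, PD = 15),
                              effect = c(gait_velocity_mps = 12), seed = 201)
  rep <- runBench(tab, benchConfig("PD_NONPD", seed = 5))
  expect_equal(rep@summary$holdout_accuracy, c(1, 1, 1))
  expect_true(all(rep@summary$cv_mean > 0.95))
})

test_that("identical seeds give identical splits and reports", {
  tab <- simulateFeatureTable(c(S = 12, PD = 12),
                              effect = c(swing_time_s = 2), seed = 202)
  r1 <- runBench(tab, benchConfig("PD_NONPD", seed = 9,
                                  classifiers = "random_forest"))
  r2 <- runBench(tab, benchConfig("PD_NONPD", seed = 9,
                                  classifiers = "random_forest"))
  expect_identical(r1@summary, r2@summary)
  expect_identical(r1@features, r2@features)
  r3 <- runBench(tab, benchConfig("PD_NONPD", seed = 10,
                                  classifiers = "random_forest"))
  expect_false(identical(r1@summary$holdout_accuracy,
                         r3@summary$holdout_accuracy))
})

test_that("the held-out partition is stratified", {
  tab <- simulateFeatureTable(c(S = 30, PD = 10), seed = 203)
  df <- pdgait:::.as_sample_df(tab)
  y <- makeLabels(df, "PD_NONPD")
  cfg <- benchConfig("PD_NONPD", seed = 3, classifiers = "random_forest",
                     selectFeatures = FALSE)
  rep <- runBench(tab, cfg)
  n_test <- rep@summary$n_test
  # per-class proportions in the test set within one sample of overall
  expect_equal(n_test, round(0.2 * 20) + round(0.2 * 60))
})

test_that("training-only fitting: held-out rows cannot leak", {
  tab <- simulateFeatureTable(c(S = 14, PD = 14),
                              effect = c(swing_time_s = 3), seed = 204)
  df <- pdgait:::.as_sample_df(tab)
  cfg <- benchConfig("PD_NONPD", seed = 4, classifiers = "random_forest")
  r1 <- runBench(df, cfg)
  # perturb the rows that land in the held-out partition and rerun: the
  # selected features and cross-validated accuracy must not move
  test_idx <- with(list(), {
    y <- makeLabels(df, "PD_NONPD")
    pdgait:::with_seed(cfg$seed, unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1, round(0.2 * length(idx))))
    })))
  })
  df2 <- df
  df2[test_idx, gaitFeatureNames()] <-
    df2[test_idx, gaitFeatureNames()] * 10 + 3
  r2 <- runBench(df2, cfg)
  expect_identical(r1@features, r2@features)
  expect_identical(r1@summary$cv_mean, r2@summary$cv_mean)
})

test_that("tiny classes reduce the fold count with a warning", {
  tab <- simulateFeatureTable(c(S = 12, PD = 3), recordingsPer = 1,
                              seed = 205)
  cfg <- benchConfig("PD_NONPD", seed = 2, classifiers = "random_forest",
                     selectFeatures = FALSE)
  expect_warning(rep <- runBench(tab, cfg), "reducing folds")
  expect_s4_class(rep, "BenchReport")
})

test_that("an over-budget grid is refused", {
  tab <- simulateFeatureTable(c(S = 10, PD = 10), seed = 206)
  cfg <- benchConfig("PD_NONPD", seed = 1, gridBudget = 10)
  expect_error(runBench(tab, cfg), "budget")
})
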