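# Mixed-model screen, correlation matrix, feature selection.

test_that("Bonferroni adjustment and significance flags are consistent", {
  tab <- simulateFeatureTable(c(A = 10, B = 10), seed = 101)
  res <- lmmScreen(tab, "group")
  expect_equal(nrow(res), 18L)
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  expect_equal(res$p_adj, pmin(1, 18 * res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_equal(res$significant, res$p_adj < 0.05)
})

test_that("an injected effect is detected and localised", {
  tab <- simulateFeatureTable(c(A = 20, B = 20),
                              effect = c(swing_time_s = 3), seed = 102)
  res <- lmmScreen(tab, "group")
  expect_true(res$significant[res$feature == "swing_time_s"])
  # other features stay mostly quiet under Bonferroni
  expect_lte(sum(res$significant), 2L)
})

test_that("the screen needs two factor levels", {
  tab <- simulateFeatureTable(c(A = 6), seed = 103)
  expect_error(lmmScreen(tab, "group"), "2 levels")
})

test_that("degenerate designs fall back to a flagged fixed-effects test", {
  # one participant per level with one row each: no within-participant
  # replication, the random intercept cannot be estimated
  tab <- simulateFeatureTable(c(A = 2, B = 2), recordingsPer = 1,
                              seed = 104)
  res <- lmmScreen(tab, "group")
  expect_true(all(res$degenerate))
  expect_true(all(is.finite(res$p_raw)))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  co <- small_cohort()
  r <- correlationMatrix(co$table)
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 1))
  expect_true(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  # the generator couples velocity and step length
  expect_gt(r["gait_velocity_mps", "step_length_m"], 0)
})

test_that("independent features show near-zero correlations", {
  set.seed(105)
  df <- as.data.frame(matrix(rnorm(2000 * 18), 2000, 18,
                             dimnames = list(NULL, gaitFeatureNames())))
  r <- correlationMatrix(df)
  off <- abs(r[upper.tri(r)])
  expect_lt(max(off), 0.1)
})

test_that("constant features yield missing correlations", {
  tab <- simulateFeatureTable(c(A = 5), seed = 106)
  df <- pdgait:::.as_sample_df(tab)
  df$steps_number <- 5
  r <- correlationMatrix(df)
  expect_true(all(is.na(r["steps_number", ])))
  expect_true(all(is.na(r[, "steps_number"])))
  expect_false(anyNA(r["swing_time_s", setdiff(gaitFeatureNames(),
                                               "steps_number")]))
})

test_that("selection keeps significant features and prunes redundancy", {
  fn <- gaitFeatureNames()
  stat <- data.frame(feature = fn, p_adj = 1, significant = FALSE)
  r <- diag(18); dimnames(r) <- list(fn, fn)
  # nothing significant: fallback to all features with a warning
  expect_warning(sel <- selectFeatures(stat, r), "falling back")
  expect_equal(sel, fn)
  # two perfectly correlated significant features: exactly one survives
  stat$significant[stat$feature %in% c("step_length_m", "stride_length_m")] <- TRUE
  stat$p_adj[stat$feature == "step_length_m"] <- 0.001
  stat$p_adj[stat$feature == "stride_length_m"] <- 0.01
  r["step_length_m", "stride_length_m"] <- 1
  r["stride_length_m", "step_length_m"] <- 1
  sel <- selectFeatures(stat, r)
  expect_equal(sel, "step_length_m")
})

test_that("a feature significant in every test is always selected", {
  fn <- gaitFeatureNames()
  r <- diag(18); dimnames(r) <- list(fn, fn)
  for (tt in gaitTestTypes()) {
    stat <- data.frame(feature = fn, p_adj = runif(18, 0.2, 1),
                       significant = FALSE)
    stat$significant[stat$feature == "swing_time_s"] <- TRUE
    stat$p_adj[stat$feature == "swing_time_s"] <- 0.01
    expect_true("swing_time_s" %in% selectFeatures(stat, r))
  }
})
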