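# Synthetic recording generator: profile lookup, ground truth, determinism.

test_that("profile lookup reproduces the published condition cells", {
  p <- makeProfile("S", testType = "WST_NORMAL")
  expect_equal(p@meanStepDuration, 0.58)
  expect_equal(p@meanStepLength, 0.69)
  expect_equal(p@stanceFraction, 0.6184)

  p <- makeProfile("PD", medicationState = "OFF", testType = "WST_SLOW")
  expect_equal(p@meanStepDuration, 0.71)
  expect_equal(p@meanStepLength, 0.50)

  p <- makeProfile("PD", severityLabel = "moderate", testType = "MTUG")
  expect_equal(p@meanStepLength, 0.51)
  # implied cadence close to the printed moderate-severity cadence
  expect_lt(abs(60 / p@meanStepDuration - 100.76), 5)
})

test_that("profile lookup rejects combinations without a condition cell", {
  expect_error(makeProfile("S", medicationState = "ON"), "configuration")
  expect_error(makeProfile("EL", severityLabel = "mild"), "configuration")
  expect_error(makeProfile("PD", medicationState = "ON",
                           severityLabel = "mild"), "configuration")
  expect_error(makeProfile("PD", severityLabel = "severe"), "configuration")
  expect_error(makeProfile("PD", testType = "STATIC"), "configuration")
})

test_that("profile invariants are enforced", {
  expect_error(gaitProfile(stanceFraction = 1.2), "stanceFraction")
  expect_error(gaitProfile(meanStepDuration = -1), "must be > 0")
  expect_error(gaitProfile(distance = 0), "must be > 0")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulateRecording(gaitProfile(), seed = 11)
  b <- simulateRecording(gaitProfile(), seed = 11)
  expect_identical(pressure(a$left), pressure(b$left))
  expect_identical(pressure(a$right), pressure(b$right))
  expect_identical(gaitEvents(a$truth), gaitEvents(b$truth))
  c <- simulateRecording(gaitProfile(), seed = 12)
  expect_false(identical(pressure(a$left), pressure(c$left)))
})

test_that("noise-free heel channels cross zero exactly at true heel strikes", {
  sim <- simulateRecording(gaitProfile(noiseSD = 0), seed = 3)
  for (side in c("left", "right")) {
    rec <- sim[[side]]
    heel <- pressure(rec)[, 1]
    t <- timeMs(rec) / 1000
    tr <- gaitEvents(sim$truth)
    hs <- tr$time_s[tr$foot == side & tr$event == "heel_strike"]
    for (h in hs) {
      i <- which(t >= h)[1]            # first sample at/after the strike
      expect_gt(heel[i], 0)
      if (i > 1) expect_equal(heel[i - 1], 0)
    }
  }
})

test_that("ground-truth events alternate and cycle in HS-FF-HR-TO order", {
  sim <- simulateRecording(gaitProfile(), seed = 5)
  expect_true(validObject(sim$truth))
  ev <- gaitEvents(sim$truth)
  lhs <- ev$time_s[ev$foot == "left" & ev$event == "heel_strike"]
  rhs <- ev$time_s[ev$foot == "right" & ev$event == "heel_strike"]
  for (k in seq_len(length(lhs) - 1))
    expect_equal(sum(rhs > lhs[k] & rhs < lhs[k + 1]), 1)
})

test_that("true step lengths sum to the walked distance within one step", {
  for (seed in 1:5) {
    sim <- simulateRecording(gaitProfile(), seed = seed)
    lens <- stepLengths(sim$truth)
    expect_equal(sum(lens), walkedDistance(sim$truth))
    over <- walkedDistance(sim$truth) - 10
    expect_gte(over, 0)
    expect_lt(over, max(lens))
  }
})

test_that("per-cycle loaded-time fraction matches the stance fraction", {
  # brute force on the signal: fraction of samples with positive foot load
  # inside each ground-truth stride
  prof <- gaitProfile(stanceFraction = 0.62, noiseSD = 0, distance = 60)
  sim <- simulateRecording(prof, seed = 17)
  rec <- sim$left
  t <- timeMs(rec) / 1000
  loaded <- rowSums(pressure(rec)) > 0
  ev <- gaitEvents(sim$truth)
  hs <- ev$time_s[ev$foot == "left" & ev$event == "heel_strike"]
  fracs <- vapply(seq_len(length(hs) - 1), function(k) {
    idx <- t >= hs[k] & t < hs[k + 1]
    mean(loaded[idx])
  }, numeric(1))
  expect_equal(mean(fracs), 0.62, tolerance = 0.02)
})

test_that("recordings validate their channel invariants", {
  sim <- simulateRecording(gaitProfile(noiseSD = 1), seed = 9)
  expect_true(validObject(sim$left))
  expect_true(all(pressure(sim$left) >= 0))
  expect_true(all(totalForce(sim$left) >= 0))
  expect_equal(unique(diff(timeMs(sim$left))), 10)
})

test_that("cohort design gives each PD participant both medication states", {
  sessions <- simulateCohort(cohortDesign(nPD = 4), tests = "WST_NORMAL",
                             recordingsPerTest = 1, seed = 2)
  meta <- data.frame(pid = vapply(sessions, `[[`, "", "participant_id"),
                     state = vapply(sessions, `[[`, "", "medication_state"))
  tab <- table(meta$pid, meta$state)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab[, "ON"] == 1 & tab[, "OFF"] == 1))
})

test_that("participant intraclass correlation rises with participantSD", {
  icc_of <- function(psd, seed) {
    sessions <- simulateCohort(cohortDesign(nAdults = 24),
                               tests = "WST_NORMAL", recordingsPerTest = 2,
                               seed = seed, participantSD = psd, noiseSD = 0)
    # mean step interval from ground truth (no detection needed)
    vals <- vapply(sessions, function(s) {
      hs <- gaitEvents(s$truth)
      mean(diff(sort(hs$time_s[hs$event == "heel_strike"])))
    }, numeric(1))
    pid <- factor(vapply(sessions, `[[`, "", "participant_id"))
    ms <- anova(lm(vals ~ pid))["Mean Sq"]
    msb <- ms[[1]][1]; msw <- ms[[1]][2]
    (msb - msw) / (msb + msw)   # two recordings per participant
  }
  expect_gt(icc_of(2, 31), icc_of(0, 31) + 0.3)
})

test_that("feature-level simulator has the requested structure", {
  tab <- simulateFeatureTable(c(A = 6, B = 6), recordingsPer = 2, seed = 4)
  expect_s4_class(tab, "GaitSampleTable")
  expect_equal(dim(tab), c(18L, 24L))
  expect_equal(sort(unique(tab$group)), c("A", "B"))
  shifted <- simulateFeatureTable(c(A = 40, B = 40),
                                  effect = c(swing_time_s = 3), seed = 4)
  df <- as.data.frame(t(SummarizedExperiment::assay(shifted)))
  df$group <- shifted$group
  gap <- mean(df$swing_time_s[df$group == "B"]) -
    mean(df$swing_time_s[df$group == "A"])
  expect_equal(gap, 3 * sqrt(0.5), tolerance = 0.2)
})
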