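# Feature extraction: analytic cases, identities, sensitivity, recovery.

test_that("a perfectly periodic walk yields the analytic phase values", {
  ev <- periodic_events(n_strides = 12, stride_s = 1.20, stance_frac = 0.60)
  cyc <- segmentCycles(ev)
  ft <- computeFeatures(cyc, ev, distance = 12 * 1.3)
  expect_equal(ft$stride_duration_s, 1.20)
  expect_equal(ft$stance_time_s, 0.72)
  expect_equal(ft$swing_time_s, 0.48)
  expect_equal(ft$stance_phase_pct, 60)
  expect_equal(ft$swing_phase_pct, 40)
  expect_equal(ft$step_duration_s, 0.60)
  # double support of a symmetric walk: (2 * stance_fraction - 1) per
  # interior cycle (the opening cycle has no preceding contralateral
  # stance, so the cohort mean sits just below the analytic value)
  interior <- which(cyc$foot == "left")[5]
  oracle <- brute_support(ev, cyc$hs[interior], cyc$next_hs[interior])
  expect_equal(unname(oracle["double"]), 0.2 * 1.20, tolerance = 1e-3)
  expect_equal(ft$double_support_time_s, 0.2 * 1.20, tolerance = 0.05)
  expect_equal(ft$single_support_time_s, 0.8 * 1.20, tolerance = 0.02)
})

test_that("support bookkeeping matches a brute-force integration oracle", {
  ev <- periodic_events(n_strides = 8, stride_s = 1.1, stance_frac = 0.63)
  cyc <- segmentCycles(ev)
  ft <- computeFeatures(cyc, ev, distance = 9)
  # average the brute-force oracle over exactly the package's cycles
  oracle <- rowMeans(vapply(seq_len(nrow(cyc)), function(k)
    brute_support(ev, cyc$hs[k], cyc$next_hs[k]), numeric(2)))
  expect_equal(ft$single_support_time_s, unname(oracle["single"]),
               tolerance = 1e-3)
  expect_equal(ft$double_support_time_s, unname(oracle["double"]),
               tolerance = 1e-3)
  # single + double support equals the stride duration exactly on periodic
  # input (no float phase: stance fraction > 0.5)
  expect_equal(ft$single_support_time_s + ft$double_support_time_s,
               ft$stride_duration_s)
})

test_that("definitional identities hold on simulated recordings", {
  for (seed in c(2, 8)) {
    sim <- simulateRecording(gaitProfile(noiseSD = 0.5), seed = seed)
    ev <- detectEvents(sim$left, sim$right)
    cyc <- segmentCycles(ev, segmentWindow(sim$truth))
    ft <- computeFeatures(cyc, ev, walkedDistance(sim$truth),
                          segmentWindow(sim$truth))
    expect_equal(ft$stance_phase_pct + ft$swing_phase_pct, 100)
    expect_equal(ft$stride_length_m, 2 * ft$step_length_m)
    expect_equal(ft$walk_ratio_mm_per_spm,
                 1000 * ft$step_length_m / ft$step_frequency_spm)
    expect_equal(ft$gait_velocity_mps,
                 ft$step_length_m * ft$step_frequency_spm / 60)
    expect_equal(ft$single_support_time_s + ft$double_support_time_s,
                 ft$stride_duration_s, tolerance = 0.03)
  }
})

test_that("the healthy-adult walk ratio comes out near 6.5 mm/step/min", {
  sim <- simulateRecording(
    gaitProfile(meanStepLength = 0.65, meanStepDuration = 0.60,
                stepLengthCV = 0, stepDurationCV = 0, noiseSD = 0),
    seed = 1)
  ev <- detectEvents(sim$left, sim$right)
  cyc <- segmentCycles(ev, segmentWindow(sim$truth))
  ft <- computeFeatures(cyc, ev, walkedDistance(sim$truth),
                        segmentWindow(sim$truth))
  expect_equal(ft$walk_ratio_mm_per_spm, 6.5, tolerance = 0.1 / 6.5)
})

test_that("distance sensitivity is proportional and small over the step range", {
  ev <- periodic_events(n_strides = 9, stride_s = 1.1, stance_frac = 0.6)
  cyc <- segmentCycles(ev)
  ft <- computeFeatures(cyc, ev, distance = 10)
  # zero delta: identical features
  same <- distanceSensitivity(ft, 10, stepDelta = 0)
  expect_equal(same$plus, ft)
  expect_equal(same$minus, ft)
  # one-step delta scales the distance-dependent features proportionally
  sens <- distanceSensitivity(ft, 10, stepDelta = 0.55)
  expect_equal(unname(sens$absDiff["gait_velocity_mps"]),
               0.55 / 10 * ft$gait_velocity_mps)
  # across the observed step-count range, +/- one step moves the step
  # length by at most 0.05 m (second-decimal stability)
  for (n in c(14.35, 16, 18.65, 22.48)) {
    ft2 <- ft
    ft2$step_length_m <- 10 / n
    s <- distanceSensitivity(ft2, 10)
    expect_lte(unname(s$absDiff["step_length_m"]), 0.05)
  }
})

test_that("temporal features fall and spatial features rise with speed", {
  feats <- lapply(c("WST_SLOW", "WST_NORMAL", "WST_HIGH"), function(tt) {
    rows <- lapply(1:4, function(i) {
      prof <- makeProfile("S", testType = tt, participantSD = 0)
      sim <- simulateRecording(prof, seed = 600 + i)
      ev <- detectEvents(sim$left, sim$right)
      cyc <- segmentCycles(ev, segmentWindow(sim$truth))
      computeFeatures(cyc, ev, walkedDistance(sim$truth),
                      segmentWindow(sim$truth))
    })
    colMeans(do.call(rbind, rows))
  })
  get <- function(name) vapply(feats, `[[`, numeric(1), name)
  for (f in c("step_duration_s", "stride_duration_s", "stance_time_s",
              "swing_time_s", "single_support_time_s",
              "double_support_time_s"))
    expect_true(all(diff(get(f)) < 0), info = f)
  for (f in c("gait_velocity_mps", "step_length_m", "stride_length_m",
              "step_frequency_spm", "swing_phase_pct"))
    expect_true(all(diff(get(f)) > 0), info = f)
})

test_that("extraction refuses a segment with no complete cycle", {
  ev <- periodic_events(n_strides = 1, stride_s = 1.2, stance_frac = 0.6)
  cyc <- segmentCycles(ev, c(0, 1.5))
  expect_error(computeFeatures(cyc, ev, 10), "feature-extraction")
})
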