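# Event detection: region loads, state machine, cycle segmentation.

test_that("region loads sum the requested channels", {
  n <- 20
  p <- matrix(0, n, 16)
  p[, 3] <- 1; p[, 7] <- 2
  rec <- insoleRecording("left", seq(0, by = 10, length.out = n), p)
  expect_equal(regionLoad(rec, 1:16), rep(3, n))
  expect_equal(regionLoad(rec, 7), rep(2, n))      # single channel: identity
  expect_equal(regionLoad(rec, c(3, 7)), rep(3, n))
  expect_equal(regionLoad(rec, 1), rep(0, n))
  expect_error(regionLoad(rec, integer(0)), "configuration")
  expect_error(regionLoad(rec, 17), "configuration")
})

test_that("noise-free detection lands within one sample of ground truth", {
  for (seed in c(1, 2)) {
    sim <- simulateRecording(gaitProfile(noiseSD = 0), seed = seed)
    ev <- detectEvents(sim$left, sim$right)
    errs <- event_errors(ev, gaitEvents(sim$truth))
    expect_true(all(is.finite(errs)))
    expect_lte(max(errs), 0.010 + 1e-9)
  }
})

test_that("an all-zero or too-short recording yields an empty event list", {
  rec <- function(ft) insoleRecording(ft, seq(0, 990, 10),
                                      matrix(0, 100, 16))
  ev <- detectEvents(rec("left"), rec("right"))
  expect_equal(nrow(ev), 0L)
})

test_that("detection is invariant to rescaling all pressures", {
  sim <- simulateRecording(gaitProfile(noiseSD = 0.4), seed = 6)
  scale_rec <- function(r, k)
    insoleRecording(foot(r), timeMs(r), pressure(r) * k,
                    totalForce = totalForce(r) * k)
  ev1 <- detectEvents(sim$left, sim$right)
  ev2 <- detectEvents(scale_rec(sim$left, 7.3), scale_rec(sim$right, 7.3))
  expect_equal(ev1, ev2)
})

test_that("NaN pressures raise a validation error", {
  sim <- simulateRecording(gaitProfile(), seed = 7)
  p <- pressure(sim$left)
  p[100, 4] <- NaN
  bad <- sim$left
  bad@pressure <- p
  expect_error(detectEvents(bad, sim$right), "validation")
})

test_that("detected sequences always respect the HS-FF-HR-TO cycle", {
  for (seed in 1:4) {
    sim <- simulateRecording(gaitProfile(noiseSD = 1.2), seed = seed)
    ev <- detectEvents(sim$left, sim$right)
    for (ft in c("left", "right")) {
      idx <- match(ev$event[ev$foot == ft], gaitEventTypes())
      if (length(idx) > 1) expect_true(all(diff(idx) %% 4 == 1))
    }
  }
})

test_that("median detection error is non-decreasing in the noise level", {
  noise <- c(0, 0.75, 2, 4)
  med <- vapply(noise, function(ns) {
    errs <- unlist(lapply(1:3, function(seed) {
      sim <- simulateRecording(gaitProfile(noiseSD = ns, distance = 15),
                               seed = 40 + seed)
      event_errors(detectEvents(sim$left, sim$right),
                   gaitEvents(sim$truth))
    }))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-9))
})

test_that("cycle segmentation matches brute-force heel-strike enumeration", {
  ev <- periodic_events(n_strides = 10, stride_s = 1.2, stance_frac = 0.6)
  cyc <- segmentCycles(ev)
  # brute force: per foot, every consecutive HS pair whose interior holds
  # FF/HR/TO and one contralateral HS
  for (ft in c("left", "right")) {
    hs <- ev$time_s[ev$foot == ft & ev$event == "heel_strike"]
    expected <- 0L
    contra <- ev$time_s[ev$foot != ft & ev$event == "heel_strike"]
    for (k in seq_len(length(hs) - 1)) {
      inner <- ev[ev$foot == ft & ev$time_s > hs[k] & ev$time_s < hs[k + 1], ]
      ok <- all(c("foot_flat", "heel_rise", "toe_off") %in% inner$event) &&
        sum(contra > hs[k] & contra < hs[k + 1]) == 1
      expected <- expected + ok
    }
    expect_equal(sum(cyc$foot == ft), expected)
  }
  # the trailing heel strike opens no complete cycle: 10 strides per foot
  expect_equal(nrow(cyc), 20L)
})

test_that("clipping the window drops the cycles it truncates", {
  ev <- periodic_events(n_strides = 6, stride_s = 1.0, stance_frac = 0.6,
                        start = 1)
  full <- segmentCycles(ev)
  # exclude the final left heel strike (at 1 + 6*1.0)
  clipped <- segmentCycles(ev, c(0, 6.9))
  expect_equal(sum(clipped$foot == "left"), sum(full$foot == "left") - 1L)
})

test_that("a stride missing its contralateral heel strike is excluded", {
  ev <- periodic_events(n_strides = 5, stride_s = 1.0, stance_frac = 0.6)
  # drop the right heel strike inside the 3rd left stride
  lhs <- ev$time_s[ev$foot == "left" & ev$event == "heel_strike"]
  drop <- ev$foot == "right" & ev$event == "heel_strike" &
    ev$time_s > lhs[3] & ev$time_s < lhs[4]
  expect_equal(sum(drop), 1L)
  cyc <- segmentCycles(ev[!drop, ])
  before <- segmentCycles(ev)
  expect_equal(sum(cyc$foot == "left"), sum(before$foot == "left") - 1L)
})

test_that("events are detected accurately under moderate noise", {
  # 5% of the peak heel-channel load, a few short recordings
  hits <- 0; total <- 0
  for (seed in 1:3) {
    sim <- simulateRecording(gaitProfile(noiseSD = 0.75, distance = 15),
                             seed = 50 + seed)
    errs <- event_errors(detectEvents(sim$left, sim$right),
                         gaitEvents(sim$truth))
    hits <- hits + sum(errs <= 0.020 + 1e-9)
    total <- total + length(errs)
  }
  expect_gte(hits / total, 0.98)
})
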