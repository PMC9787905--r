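# Shared fixtures: analytic event builders and brute-force oracles.

# Perfectly periodic bilateral event table: left heel strikes at start,
# start + stride, ...; right offset by stride/2; stance = stance_frac of the
# stride with foot flat at 25% and heel rise at 70% of stance.
periodic_events <- function(n_strides = 10, stride_s = 1.2,
                            stance_frac = 0.6, start = 1) {
  build <- function(foot, offset) {
    hs <- start + offset + (seq_len(n_strides + 1) - 1) * stride_s
    st <- stance_frac * stride_s
    data.frame(
      foot = foot,
      event = rep(gaitEventTypes(), times = length(hs)),
      time_s = as.vector(rbind(hs, hs + 0.25 * st, hs + 0.70 * st, hs + st)),
      stringsAsFactors = FALSE)
  }
  ev <- rbind(build("left", 0), build("right", stride_s / 2))
  ev[order(ev$foot, ev$time_s), ]
}

# Brute-force single/double-support oracle: numerically integrate the
# number of loaded feet on a fine grid, independent of the package's
# interval arithmetic.
brute_support <- function(events, from, to, dt = 1e-4) {
  stance <- do.call(rbind, lapply(c("left", "right"), function(ft) {
    sub <- events[events$foot == ft, ]
    sub <- sub[order(sub$time_s), ]
    hs <- sub$time_s[sub$event == "heel_strike"]
    toff <- sub$time_s[sub$event == "toe_off"]
    ends <- vapply(hs, function(x) {
      nxt <- toff[toff > x]
      if (length(nxt)) nxt[1] else NA_real_
    }, numeric(1))
    data.frame(start = hs[!is.na(ends)], end = ends[!is.na(ends)])
  }))
  grid <- seq(from, to - dt / 2, by = dt)
  nload <- vapply(grid, function(g)
    sum(stance$start <= g & stance$end > g), numeric(1))
  c(single = sum(nload == 1) * dt, double = sum(nload >= 2) * dt)
}

# Match each truth event to the nearest detected event of the same foot and
# type; returns the absolute time errors in seconds.
event_errors <- function(detected, truth_events) {
  errs <- numeric(0)
  for (ft in c("left", "right")) {
    for (tp in gaitEventTypes()) {
      tt <- truth_events$time_s[truth_events$foot == ft &
                                  truth_events$event == tp]
      dd <- detected$time_s[detected$foot == ft & detected$event == tp]
      if (!length(tt)) next
      errs <- c(errs, vapply(tt, function(x)
        if (length(dd)) min(abs(dd - x)) else Inf, numeric(1)))
    }
  }
  errs
}

# Small simulated cohort reused across tests (lazily memoised).
local({
  cache <- new.env()
  small_cohort <<- function() {
    if (is.null(cache$sessions)) {
      cache$sessions <- simulateCohort(
        cohortDesign(nAdults = 3, nPD = 3), tests = "WST_NORMAL",
        recordingsPerTest = 2, seed = 421)
      cache$table <- extractFeatureTable(cache$sessions)
    }
    list(sessions = cache$sessions, table = cache$table)
  }
})
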