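# Extraction of the 18 temporal and spatial gait features.

# Integrate the number of loaded feet over [from, to) given per-foot stance
# intervals; returns time with exactly one foot loaded and with both loaded.
.support_times <- function(stance, from, to) {
  # stance: data.frame(start, end) over both feet
  bounds <- sort(unique(c(from, to,
                          stance$start[stance$start > from & stance$start < to],
                          stance$end[stance$end > from & stance$end < to])))
  single <- 0; double <- 0
  for (j in seq_len(length(bounds) - 1L)) {
    mid <- (bounds[j] + bounds[j + 1L]) / 2
    nload <- sum(stance$start <= mid & stance$end > mid)
    w <- bounds[j + 1L] - bounds[j]
    if (nload == 1L) single <- single + w
    if (nload >= 2L) double <- double + w
  }
  c(single = single, double = double)
}

#' Compute the 18 gait features of one recording segment
#'
#' Temporal conventions: a step is the interval from a contralateral heel
#' strike to the next ipsilateral heel strike; stride duration is the
#' ipsilateral heel-strike interval; stance is heel strike to toe off and
#' swing its complement; single/double support are the per-cycle times with
#' exactly one / both feet loaded. Phase-temporal features are normalised by
#' the stride duration (percentages of the gait cycle). Spatial conventions:
#' the walked distance is divided over the step intervals in the window, so
#' `steps_number` counts step intervals (heel strikes minus one), gait
#' velocity is distance over the first-to-last heel-strike time, stride
#' length is twice the step length, cadence is steps per minute, and the
#' walk ratio is step length in mm over cadence.
#'
#' @param cycles Complete strides from [segmentCycles()].
#' @param events Event `data.frame` for the same window (used for step
#'   intervals and support bookkeeping).
#' @param distance Walked distance in metres for the segment.
#' @param window Optional length-2 window (s) to clip `events`; use the
#'   window passed to [segmentCycles()].
#' @return One-row `data.frame` with the columns of [gaitFeatureNames()].
#' @examples
#' sim <- simulateRecording(gaitProfile(noiseSD = 0), seed = 1)
#' ev <- detectEvents(sim$left, sim$right)
#' cyc <- segmentCycles(ev, segmentWindow(sim$truth))
#' computeFeatures(cyc, ev, walkedDistance(sim$truth))
#' @export
computeFeatures <- function(cycles, events, distance, window = NULL) {
  if (!is.null(window))
    events <- events[events$time_s >= window[1] & events$time_s <= window[2], ]
  if (nrow(cycles) == 0L || !any(cycles$foot == "left") ||
      !any(cycles$foot == "right"))
    stop("feature-extraction error: no complete gait cycle per foot in the ",
         "segment", call. = FALSE)
  stopifnot(is.numeric(distance), distance > 0)

  hs <- events[events$event == "heel_strike", ]
  hs <- hs[order(hs$time_s), ]
  n_hs <- nrow(hs)
  if (n_hs < 2L)
    stop("feature-extraction error: fewer than two heel strikes in the ",
         "window", call. = FALSE)

  # step intervals: contralateral HS -> ipsilateral HS (alternating feet)
  alt <- hs$foot[-1] != hs$foot[-n_hs]
  step_dur <- diff(hs$time_s)[alt]
  step_foot <- hs$foot[-1][alt]
  left_step <- mean(step_dur[step_foot == "left"])
  right_step <- mean(step_dur[step_foot == "right"])

  stride <- cycles$next_hs - cycles$hs
  stance <- cycles$to - cycles$hs
  swing <- cycles$next_hs - cycles$to

  # stance episodes of both feet for support bookkeeping
  episodes <- do.call(rbind, lapply(c("left", "right"), function(ft) {
    sub <- events[events$foot == ft, ]
    sub <- sub[order(sub$time_s), ]
    h <- sub$time_s[sub$event == "heel_strike"]
    to <- sub$time_s[sub$event == "toe_off"]
    ends <- vapply(h, function(x) {
      nxt <- to[to > x]
      if (length(nxt)) nxt[1] else NA_real_
    }, numeric(1))
    data.frame(start = h[!is.na(ends)], end = ends[!is.na(ends)])
  }))
  supp <- vapply(seq_len(nrow(cycles)), function(k)
    .support_times(episodes, cycles$hs[k], cycles$next_hs[k]), numeric(2))
  single_t <- mean(supp["single", ])
  double_t <- mean(supp["double", ])

  mean_stride <- mean(stride)
  steps_number <- n_hs - 1L
  walk_time <- hs$time_s[n_hs] - hs$time_s[1]
  velocity <- distance / walk_time
  step_length <- distance / steps_number
  step_freq <- steps_number / walk_time * 60

  data.frame(
    left_step_duration_s = left_step,
    right_step_duration_s = right_step,
    step_duration_s = mean(step_dur),
    stride_duration_s = mean_stride,
    steps_number = steps_number,
    single_support_time_s = single_t,
    double_support_time_s = double_t,
    stance_time_s = mean(stance),
    swing_time_s = mean(swing),
    single_support_pct = 100 * single_t / mean_stride,
    double_support_pct = 100 * double_t / mean_stride,
    stance_phase_pct = 100 * mean(stance) / mean_stride,
    swing_phase_pct = 100 * mean(swing) / mean_stride,
    gait_velocity_mps = velocity,
    step_length_m = step_length,
    stride_length_m = 2 * step_length,
    step_frequency_spm = step_freq,
    walk_ratio_mm_per_spm = 1000 * step_length / step_freq)
}

#' Sensitivity of the distance-dependent features to one step of distance
#'
#' The straight-line distance is known only to within one step (participants
#' turn slightly before or after the mark), so the four distance-dependent
#' features (gait velocity, step length, stride length, walk ratio) are
#' recomputed with the distance shifted by plus and minus one mean step
#' length, and the elementwise absolute differences reported.
#'
#' @param features One-row feature `data.frame` from [computeFeatures()].
#' @param distance The distance used to compute `features` (m).
#' @param stepDelta Distance shift in metres; default one mean step length.
#' @return List with elements `plus`, `minus` (recomputed feature rows) and
#'   `absDiff` (absolute differences, distance-dependent features only).
#' @export
distanceSensitivity <- function(features, distance,
                                stepDelta = features$step_length_m) {
  stopifnot(nrow(features) == 1L, distance > 0, stepDelta >= 0,
            stepDelta < distance)
  dep <- c("gait_velocity_mps", "step_length_m", "stride_length_m",
           "walk_ratio_mm_per_spm")
  rescale <- function(fac) {
    out <- features
    out[dep] <- features[dep] * fac
    out
  }
  plus <- rescale((distance + stepDelta) / distance)
  minus <- rescale((distance - stepDelta) / distance)
  diffs <- abs(plus[dep] - minus[dep]) / 2
  list(plus = plus, minus = minus, absDiff = unlist(diffs))
}
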