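# Gait-event detection: hysteresis state machine over region loads.

#' Sum the pressure of a sensor region
#'
#' @param rec An [InsoleRecording-class].
#' @param region Integer indices (1..16) of the region's pressure channels.
#' @return Numeric vector of the summed region pressure, one per sample.
#' @examples
#' rec <- insoleRecording("left", seq(0, 90, 10), matrix(1, 10, 16))
#' regionLoad(rec, 1:4)[1]   # 4
#' @export
regionLoad <- function(rec, region) {
  stopifnot(is(rec, "InsoleRecording"))
  region <- as.integer(region)
  if (length(region) < 1L)
    stop("configuration error: empty sensor region", call. = FALSE)
  if (any(region < 1L | region > 16L))
    stop("configuration error: region channels must lie in 1..16",
         call. = FALSE)
  rowSums(pressure(rec)[, region, drop = FALSE])
}

# Internal per-foot state machine. Events are timestamped at the first
# sample past threshold (no sub-sample interpolation; 10 ms native
# resolution at 100 Hz). Candidate phases shorter than the debounce are
# rolled back: the event is discarded and the machine returns to the
# previous state.
.detect_foot <- function(rec, cfg) {
  heel <- regionLoad(rec, cfg@heelChannels)
  fore <- regionLoad(rec, cfg@forefootChannels)
  if (anyNA(heel) || anyNA(fore))
    stop("validation error: NaN/NA pressures", call. = FALSE)
  t <- timeMs(rec) / 1000
  rng_h <- range(heel); rng_f <- range(fore)
  if (diff(rng_h) <= 1e-12 || diff(rng_f) <= 1e-12)
    return(data.frame(foot = character(), event = character(),
                      time_s = numeric(), stringsAsFactors = FALSE))
  on_h <- rng_h[1] + cfg@onThreshold * diff(rng_h)
  off_h <- rng_h[1] + cfg@offThreshold * diff(rng_h)
  on_f <- rng_f[1] + cfg@onThreshold * diff(rng_f)
  off_f <- rng_f[1] + cfg@offThreshold * diff(rng_f)
  debounce <- ceiling(cfg@debounceMs / 1000 * samplingRate(rec))

  ev_type <- character(0); ev_time <- numeric(0)
  emit <- function(type, i) {
    ev_type[length(ev_type) + 1L] <<- type
    ev_time[length(ev_time) + 1L] <<- t[i]
  }
  rollback <- function() {
    ev_type <<- ev_type[-length(ev_type)]
    ev_time <<- ev_time[-length(ev_time)]
  }

  state <- "unknown"; phase_start <- 1L
  for (i in seq_along(t)) {
    h <- heel[i]; f <- fore[i]
    if (state == "unknown") {
      if (h < off_h && f < off_f) state <- "swing"
    } else if (state == "swing") {
      if (h >= on_h) {
        emit("heel_strike", i); state <- "early"; phase_start <- i
      }
    } else if (state == "early") {
      if (f >= on_f) {
        emit("foot_flat", i); state <- "flat"; phase_start <- i
      } else if (h < off_h && (i - phase_start) < debounce) {
        rollback(); state <- "swing"
      }
    } else if (state == "flat") {
      if (h < off_h) {
        emit("heel_rise", i); state <- "late"; phase_start <- i
      } else if (f < off_f && (i - phase_start) < debounce) {
        rollback(); state <- "early"; phase_start <- i
      }
    } else if (state == "late") {
      if (f < off_f) {
        emit("toe_off", i); state <- "swing"; phase_start <- i
      } else if (h >= on_h && (i - phase_start) < debounce) {
        rollback(); state <- "flat"; phase_start <- i
      }
    }
  }
  data.frame(foot = foot(rec), event = ev_type, time_s = ev_time,
             stringsAsFactors = FALSE)
}

.assert_cycle_order <- function(events) {
  for (ft in unique(events$foot)) {
    idx <- match(events$event[events$foot == ft], gaitEventTypes())
    if (length(idx) > 1L && !all(diff(idx) %% 4 == 1))
      stop("internal error: detected events violate the HS-FF-HR-TO cycle",
           call. = FALSE)
  }
  invisible(events)
}

#' Detect gait events from a bilateral recording
#'
#' Annotates heel strike, foot flat, heel rise and toe off per foot with a
#' hysteresis state machine over the heel and forefoot region loads: heel
#' strike when the heel load crosses `onThreshold` upward from swing, foot
#' flat when the forefoot load also exceeds it, heel rise when the heel load
#' falls below `offThreshold` while the forefoot remains loaded, toe off
#' when the forefoot load falls below `offThreshold`. Thresholds are
#' fractions of each region's per-recording dynamic range, so detection is
#' invariant to rescaling all pressures. Candidate phases shorter than the
#' debounce are rolled back.
#'
#' @param left,right [InsoleRecording-class] objects for the two feet.
#' @param cfg A [DetectorConfig-class] (default [detectorConfig()]).
#' @return `data.frame` with columns `foot`, `event`, `time_s`, ordered by
#'   foot then time; the per-foot sequence always satisfies the cyclic
#'   HS -> FF -> HR -> TO order. A recording shorter than one full cycle
#'   yields an empty frame.
#' @examples
#' sim <- simulateRecording(gaitProfile(noiseSD = 0), seed = 1)
#' ev <- detectEvents(sim$left, sim$right)
#' head(ev)
#' @export
detectEvents <- function(left, right, cfg = detectorConfig()) {
  stopifnot(is(left, "InsoleRecording"), is(right, "InsoleRecording"))
  validObject(cfg)
  ev <- rbind(.detect_foot(left, cfg), .detect_foot(right, cfg))
  ev <- ev[order(ev$foot, ev$time_s), ]
  rownames(ev) <- NULL
  .assert_cycle_order(ev)
}

#' Segment detected events into complete gait cycles
#'
#' Clips events to the straight-line window, then builds per-foot strides
#' (heel strike to next heel strike). A stride is kept only if it is
#' complete: it contains its own foot flat, heel rise and toe off in order
#' and exactly one contralateral heel strike; leading/trailing incomplete
#' cycles are discarded.
#'
#' @param events Event `data.frame` (columns `foot`, `event`, `time_s`).
#' @param window Numeric length-2 window in seconds (e.g. from
#'   [segmentWindow()]); `NULL` keeps all events.
#' @return `data.frame` with one row per complete stride: `foot`, `hs`,
#'   `ff`, `hr`, `to`, `next_hs`, `contra_hs` (times in seconds). Zero
#'   complete cycles yield an empty frame.
#' @export
segmentCycles <- function(events, window = NULL) {
  stopifnot(all(c("foot", "event", "time_s") %in% names(events)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    events <- events[events$time_s >= window[1] & events$time_s <= window[2], ]
  }
  empty <- data.frame(foot = character(), hs = numeric(), ff = numeric(),
                      hr = numeric(), to = numeric(), next_hs = numeric(),
                      contra_hs = numeric(), stringsAsFactors = FALSE)
  if (nrow(events) == 0L) return(empty)
  out <- list()
  for (ft in c("left", "right")) {
    own <- events[events$foot == ft, ]
    own <- own[order(own$time_s), ]
    contra_hs <- events$time_s[events$foot != ft &
                                 events$event == "heel_strike"]
    hs_t <- own$time_s[own$event == "heel_strike"]
    if (length(hs_t) < 2L) next
    for (k in seq_len(length(hs_t) - 1L)) {
      a <- hs_t[k]; b <- hs_t[k + 1L]
      inside <- own[own$time_s > a & own$time_s < b, ]
      ff <- inside$time_s[inside$event == "foot_flat"]
      hr <- inside$time_s[inside$event == "heel_rise"]
      to <- inside$time_s[inside$event == "toe_off"]
      ch <- contra_hs[contra_hs > a & contra_hs < b]
      complete <- length(ff) == 1L && length(hr) == 1L && length(to) == 1L &&
        length(ch) == 1L && a < ff && ff < hr && hr < to && to < b
      if (complete)
        out[[length(out) + 1L]] <- data.frame(
          foot = ft, hs = a, ff = ff, hr = hr, to = to, next_hs = b,
          contra_hs = ch, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  cycles <- do.call(rbind, out)
  cycles[order(cycles$foot, cycles$hs), , drop = FALSE]
}
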