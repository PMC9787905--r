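# S4 classes for the central data objects.

#' Canonical vocabularies
#'
#' `gaitEventTypes()` returns the four pressure-defined gait landmarks in
#' their within-stance order; `gaitTestTypes()` the supported walking tests
#' (Walk Straight and Turn at slow/normal/high self-selected speed, and the
#' modified Timed Up and Go); `gaitGroups()` the participant groups (S =
#' adults, EL = elderly, PD = patients).
#'
#' @return Character vector of level names.
#' @export
gaitEventTypes <- function() c("heel_strike", "foot_flat", "heel_rise", "toe_off")

#' @rdname gaitEventTypes
#' @export
gaitTestTypes <- function() c("WST_SLOW", "WST_NORMAL", "WST_HIGH", "MTUG")

#' @rdname gaitEventTypes
#' @export
gaitGroups <- function() c("S", "EL", "PD")

#' Names of the 18 temporal and spatial gait features
#'
#' The canonical column order used by every feature table in the package:
#' left/right/overall step duration, stride duration, steps number, single
#' and double support time, stance and swing time, the four gait-cycle
#' percentages, gait velocity, step and stride length, step frequency
#' (cadence) and the walk ratio (step length in mm over cadence).
#'
#' @return Character vector of length 18.
#' @export
gaitFeatureNames <- function() {
  c("left_step_duration_s", "right_step_duration_s", "step_duration_s",
    "stride_duration_s", "steps_number", "single_support_time_s",
    "double_support_time_s", "stance_time_s", "swing_time_s",
    "single_support_pct", "double_support_pct", "stance_phase_pct",
    "swing_phase_pct", "gait_velocity_mps", "step_length_m",
    "stride_length_m", "step_frequency_spm", "walk_ratio_mm_per_spm")
}

# ---------------------------------------------------------------------------
# InsoleRecording

#' InsoleRecording: one foot's multichannel insole time series
#'
#' Holds the raw per-foot recording unit: timestamps in integer milliseconds,
#' 16 pressure channels (N/cm^2), 3-axis acceleration (g), 3-axis angular
#' rate (dps), computed total force (N) and centre of pressure (unitless
#' insole coordinates), sampled at `samplingRate` Hz (100 by default).
#'
#' @slot foot `"left"` or `"right"`.
#' @slot samplingRate Sampling rate in Hz.
#' @slot timeMs Integer milliseconds, strictly increasing, spacing consistent
#'   with the sampling rate within 1 ms jitter.
#' @slot pressure Numeric matrix, samples x 16 channels, non-negative.
#' @slot accel Numeric matrix, samples x 3.
#' @slot gyro Numeric matrix, samples x 3.
#' @slot totalForce Non-negative numeric vector.
#' @slot cop Numeric matrix, samples x 2 (x, y).
#' @export
setClass("InsoleRecording",
  representation(foot = "character", samplingRate = "numeric",
                 timeMs = "numeric", pressure = "matrix", accel = "matrix",
                 gyro = "matrix", totalForce = "numeric", cop = "matrix"))

setValidity("InsoleRecording", function(object) {
  msg <- character()
  if (!length(object@foot) == 1L || !object@foot %in% c("left", "right"))
    msg <- c(msg, "foot must be 'left' or 'right'")
  n <- length(object@timeMs)
  if (n < 2L) msg <- c(msg, "recording must contain at least 2 samples")
  lens <- c(nrow(object@pressure), nrow(object@accel), nrow(object@gyro),
            length(object@totalForce), nrow(object@cop))
  if (any(lens != n))
    msg <- c(msg, "all channel arrays must share the timestamp length")
  if (ncol(object@pressure) != 16L)
    msg <- c(msg, "pressure must have 16 channels")
  if (ncol(object@accel) != 3L || ncol(object@gyro) != 3L)
    msg <- c(msg, "accel and gyro must have 3 channels")
  if (ncol(object@cop) != 2L) msg <- c(msg, "cop must have 2 columns")
  if (n >= 2L) {
    dt <- diff(object@timeMs)
    if (any(dt <= 0)) msg <- c(msg, "time_ms must be strictly increasing")
    nominal <- 1000 / object@samplingRate
    if (any(abs(dt - nominal) > 1 + 1e-9))
      msg <- c(msg, sprintf(
        "time step inconsistent with sampling rate %g Hz (>1 ms jitter)",
        object@samplingRate))
  }
  if (anyNA(object@pressure)) msg <- c(msg, "pressure contains NA")
  else if (any(object@pressure < 0)) msg <- c(msg, "pressures must be >= 0")
  if (!anyNA(object@totalForce) && any(object@totalForce < 0))
    msg <- c(msg, "total force must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an InsoleRecording
#'
#' @param foot `"left"` or `"right"`.
#' @param timeMs Integer milliseconds, strictly increasing.
#' @param pressure Samples x 16 matrix of pressures (N/cm^2).
#' @param accel,gyro Samples x 3 IMU matrices; default zero filler.
#' @param totalForce Total normal force (N); default row sums of `pressure`
#'   scaled by a nominal per-sensor area.
#' @param cop Samples x 2 centre-of-pressure matrix; default centred.
#' @param samplingRate Sampling rate in Hz (default 100).
#' @return An [InsoleRecording-class] object.
#' @examples
#' rec <- insoleRecording("left", seq(0, 90, by = 10),
#'                        matrix(0, 10, 16))
#' nSamples(rec)
#' @export
insoleRecording <- function(foot, timeMs, pressure,
                            accel = NULL, gyro = NULL, totalForce = NULL,
                            cop = NULL, samplingRate = 100) {
  n <- length(timeMs)
  pressure <- as.matrix(pressure)
  if (is.null(accel)) accel <- matrix(0, n, 3)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  if (is.null(totalForce)) totalForce <- rowSums(pressure) * 8
  if (is.null(cop)) cop <- matrix(0.5, n, 2)
  new("InsoleRecording", foot = foot, samplingRate = samplingRate,
      timeMs = as.numeric(timeMs), pressure = pressure,
      accel = as.matrix(accel), gyro = as.matrix(gyro),
      totalForce = as.numeric(totalForce), cop = as.matrix(cop))
}

# ---------------------------------------------------------------------------
# GaitProfile

#' GaitProfile: generator parameters for one simulated walking condition
#'
#' Bundles the condition labels with the gait parameters the simulator
#' realises: mean step duration and its step-to-step coefficient of
#' variation, left/right asymmetry, the stance fraction of the gait cycle,
#' the (derived) double-support fraction, mean step length and its CV, the
#' walked distance, the between-participant random-effect multiplier and the
#' pressure noise SD.
#'
#' @slot groupLabel `"S"`, `"EL"` or `"PD"`.
#' @slot medicationState `"ON"`, `"OFF"` or `NA`.
#' @slot severityLabel `"normal"`, `"mild"`, `"moderate"`, `"severe"` or `NA`.
#' @slot testType One of [gaitTestTypes()].
#' @slot meanStepDuration Mean step duration in seconds.
#' @slot stepDurationCV Step-to-step CV of step duration (unitless).
#' @slot asymmetryRatio Left/right mean step duration ratio.
#' @slot stanceFraction Fraction of the gait cycle in stance (0, 1).
#' @slot doubleSupportFraction Fraction of the cycle in double support,
#'   `2 * stanceFraction - 1` for alternating symmetric gait.
#' @slot meanStepLength Mean step length in metres.
#' @slot stepLengthCV Step-to-step CV of step length.
#' @slot distance Straight-line distance to walk in metres (default 10).
#' @slot participantSD Between-participant multiplier on the profile CVs used
#'   for random effects (0 = no participant heterogeneity).
#' @slot noiseSD Additive Gaussian pressure noise SD in N/cm^2.
#' @export
setClass("GaitProfile",
  representation(groupLabel = "character", medicationState = "character",
                 severityLabel = "character", testType = "character",
                 meanStepDuration = "numeric", stepDurationCV = "numeric",
                 asymmetryRatio = "numeric", stanceFraction = "numeric",
                 doubleSupportFraction = "numeric", meanStepLength = "numeric",
                 stepLengthCV = "numeric", distance = "numeric",
                 participantSD = "numeric", noiseSD = "numeric"))

setValidity("GaitProfile", function(object) {
  msg <- character()
  if (!(object@stanceFraction > 0 && object@stanceFraction < 1))
    msg <- c(msg, "stanceFraction must lie in (0, 1)")
  if (!(object@doubleSupportFraction >= 0 &&
        object@doubleSupportFraction < object@stanceFraction))
    msg <- c(msg, "doubleSupportFraction must lie in [0, stanceFraction)")
  pos <- c(meanStepDuration = object@meanStepDuration,
           meanStepLength = object@meanStepLength,
           distance = object@distance,
           asymmetryRatio = object@asymmetryRatio)
  if (any(pos <= 0))
    msg <- c(msg, paste0(names(pos)[pos <= 0], " must be > 0",
                         collapse = "; "))
  nonneg <- c(stepDurationCV = object@stepDurationCV,
              stepLengthCV = object@stepLengthCV,
              participantSD = object@participantSD, noiseSD = object@noiseSD)
  if (any(nonneg < 0))
    msg <- c(msg, paste0(names(nonneg)[nonneg < 0], " must be >= 0",
                         collapse = "; "))
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GroundTruth

#' GroundTruth: exact event times and step lengths of a simulated recording
#'
#' @slot events `data.frame` with columns `foot`, `event`, `time_s`; per foot
#'   the events cycle strictly heel_strike -> foot_flat -> heel_rise ->
#'   toe_off with strictly increasing times.
#' @slot stepLengths True per-step lengths in metres (one per step interval).
#' @slot segmentStart,segmentEnd Straight-line window in seconds.
#' @slot distance True walked distance in metres (sum of step lengths).
#' @export
setClass("GroundTruth",
  representation(events = "data.frame", stepLengths = "numeric",
                 segmentStart = "numeric", segmentEnd = "numeric",
                 distance = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  ev <- object@events
  if (!all(c("foot", "event", "time_s") %in% names(ev)))
    return("events must have columns foot, event, time_s")
  if (!all(ev$event %in% gaitEventTypes()))
    msg <- c(msg, "unknown event types")
  for (ft in unique(ev$foot)) {
    sub <- ev[ev$foot == ft, ]
    sub <- sub[order(sub$time_s), ]
    if (any(diff(sub$time_s) <= 0))
      msg <- c(msg, sprintf("%s-foot event times not strictly increasing", ft))
    idx <- match(sub$event, gaitEventTypes())
    expected <- ((idx[1] - 1 + seq_along(idx) - 1) %% 4) + 1
    if (!all(idx == expected))
      msg <- c(msg, sprintf("%s-foot events violate the HS-FF-HR-TO cycle", ft))
  }
  if (abs(sum(object@stepLengths) - object@distance) > 1e-8)
    msg <- c(msg, "distance must equal the sum of step lengths")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DetectorConfig

#' DetectorConfig: parameters of the gait-event state machine
#'
#' Thresholds are fractions of each region's per-recording dynamic range so
#' that detection is invariant to rescaling all pressures; hysteresis
#' (`offThreshold < onThreshold`) plus a debounce window suppress spurious
#' crossings.
#'
#' @slot heelChannels,forefootChannels Integer indices (1..16) of the
#'   pressure channels aggregated into the heel / forefoot region loads.
#' @slot onThreshold,offThreshold Fractions of the region dynamic range;
#'   `0 < offThreshold < onThreshold < 1`.
#' @slot debounceMs Minimum phase duration in milliseconds; candidate phases
#'   shorter than this are rolled back.
#' @export
setClass("DetectorConfig",
  representation(heelChannels = "integer", forefootChannels = "integer",
                 onThreshold = "numeric", offThreshold = "numeric",
                 debounceMs = "numeric"))

setValidity("DetectorConfig", function(object) {
  msg <- character()
  if (length(object@heelChannels) < 1L || length(object@forefootChannels) < 1L)
    msg <- c(msg, "configuration error: region channel sets must be non-empty")
  chans <- c(object@heelChannels, object@forefootChannels)
  if (any(chans < 1L | chans > 16L))
    msg <- c(msg, "channel indices must lie in 1..16")
  if (!(object@offThreshold > 0 && object@offThreshold < object@onThreshold &&
        object@onThreshold < 1))
    msg <- c(msg, "need 0 < offThreshold < onThreshold < 1")
  if (object@debounceMs < 10)
    msg <- c(msg, "debounce must cover at least one sample (>= 10 ms at 100 Hz)")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectorConfig
#'
#' Defaults: heel region = channels 1-4, forefoot region = channels 10-16
#' (the package's published sensor-region map, configurable), thresholds at
#' 10% (on) and 5% (off) of the region dynamic range, 50 ms debounce.
#'
#' @param heelChannels,forefootChannels Pressure channel indices per region.
#' @param onThreshold,offThreshold Hysteresis thresholds as fractions of the
#'   per-recording region dynamic range.
#' @param debounceMs Minimum phase duration in ms.
#' @return A [DetectorConfig-class] object.
#' @examples
#' detectorConfig()
#' @export
detectorConfig <- function(heelChannels = 1:4, forefootChannels = 10:16,
                           onThreshold = 0.10, offThreshold = 0.05,
                           debounceMs = 50) {
  new("DetectorConfig", heelChannels = as.integer(heelChannels),
      forefootChannels = as.integer(forefootChannels),
      onThreshold = onThreshold, offThreshold = offThreshold,
      debounceMs = debounceMs)
}

# ---------------------------------------------------------------------------
# GaitSampleTable (SummarizedExperiment subclass)

#' GaitSampleTable: the feature x sample matrix feeding statistics and
#' classification
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single `"features"` assay holds the 18 gait features (rows) for each
#' recording (columns); `colData` carries `participant_id`, `group`,
#' `medication_state`, `severity_level`, `test_type` and `recording_index`.
#'
#' @export
setClass("GaitSampleTable", contains = "SummarizedExperiment")

setValidity("GaitSampleTable", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  if (!identical(rownames(object), gaitFeatureNames()))
    msg <- c(msg, "assay rows must be the 18 canonical gait features, in order")
  need <- c("participant_id", "group", "test_type")
  miss <- setdiff(need, names(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Build a GaitSampleTable from a feature data.frame
#'
#' @param features `data.frame` with one row per recording containing the 18
#'   columns of [gaitFeatureNames()] (extra identifier columns are moved to
#'   `colData`).
#' @param meta Optional `data.frame` of per-recording metadata (same row
#'   order); must include `participant_id`, `group` and `test_type`. Columns
#'   of `features` that are not features are used when `meta` is `NULL`.
#' @return A [GaitSampleTable-class].
#' @examples
#' ft <- as.data.frame(matrix(rnorm(36), 2, 18,
#'        dimnames = list(NULL, gaitFeatureNames())))
#' ft$participant_id <- c("P1", "P2"); ft$group <- "S"
#' ft$test_type <- "WST_NORMAL"
#' gaitSampleTable(ft)
#' @export
gaitSampleTable <- function(features, meta = NULL) {
  features <- as.data.frame(features)
  fn <- gaitFeatureNames()
  miss <- setdiff(fn, names(features))
  if (length(miss))
    stopf("schema error: missing feature columns: %s",
          paste(miss, collapse = ", "))
  if (is.null(meta)) {
    meta <- features[, setdiff(names(features), fn), drop = FALSE]
  }
  for (col in c("medication_state", "severity_level", "recording_index")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  need <- c("participant_id", "group", "test_type")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("validation error: missing metadata columns: %s",
          paste(miss, collapse = ", "))
  mat <- t(as.matrix(features[, fn, drop = FALSE]))
  if (anyNA(mat))
    stop("validation error: feature values contain NA", call. = FALSE)
  colnames(mat) <- rownames(meta) <- sprintf("rec%03d", seq_len(ncol(mat)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), colData = S4Vectors::DataFrame(meta))
  new("GaitSampleTable", se)
}

# ---------------------------------------------------------------------------
# BenchReport

#' BenchReport: result of one classification bench run
#'
#' @slot task Classification task identifier.
#' @slot testType Walking test the samples came from.
#' @slot summary `data.frame` with one row per classifier: cross-validation
#'   mean/SD accuracy, held-out accuracy, number of training/test samples.
#' @slot params Named list of chosen hyperparameters per classifier.
#' @slot features Character vector of selected feature names.
#' @slot recall Named list of per-class held-out recall per classifier.
#' @export
setClass("BenchReport",
  representation(task = "character", testType = "character",
                 summary = "data.frame", params = "list",
                 features = "character", recall = "list"))
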