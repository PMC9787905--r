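# Generics, accessors and show methods.

#' Accessors for InsoleRecording and GroundTruth objects
#'
#' `foot()`, `samplingRate()`, `timeMs()`, `pressure()`, `totalForce()` and
#' `nSamples()` read the corresponding recording slots; `gaitEvents()`
#' returns a ground truth's event table and `stepLengths()` its true
#' per-step lengths.
#'
#' @param object An [InsoleRecording-class] or [GroundTruth-class].
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("foot", function(object) standardGeneric("foot"))
#' @rdname accessors
#' @export
setMethod("foot", "InsoleRecording", function(object) object@foot)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "InsoleRecording", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setGeneric("timeMs", function(object) standardGeneric("timeMs"))
#' @rdname accessors
#' @export
setMethod("timeMs", "InsoleRecording", function(object) object@timeMs)

#' @rdname accessors
#' @export
setGeneric("pressure", function(object) standardGeneric("pressure"))
#' @rdname accessors
#' @export
setMethod("pressure", "InsoleRecording", function(object) object@pressure)

#' @rdname accessors
#' @export
setGeneric("totalForce", function(object) standardGeneric("totalForce"))
#' @rdname accessors
#' @export
setMethod("totalForce", "InsoleRecording", function(object) object@totalForce)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "InsoleRecording", function(object) length(object@timeMs))

#' @rdname accessors
#' @export
setGeneric("gaitEvents", function(object) standardGeneric("gaitEvents"))
#' @rdname accessors
#' @export
setMethod("gaitEvents", "GroundTruth", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("stepLengths", function(object) standardGeneric("stepLengths"))
#' @rdname accessors
#' @export
setMethod("stepLengths", "GroundTruth", function(object) object@stepLengths)

#' @rdname accessors
#' @export
setGeneric("segmentWindow", function(object) standardGeneric("segmentWindow"))
#' @rdname accessors
#' @export
setMethod("segmentWindow", "GroundTruth",
          function(object) c(object@segmentStart, object@segmentEnd))

#' @rdname accessors
#' @export
setGeneric("walkedDistance", function(object) standardGeneric("walkedDistance"))
#' @rdname accessors
#' @export
setMethod("walkedDistance", "GroundTruth", function(object) object@distance)

setMethod("show", "InsoleRecording", function(object) {
  cat(sprintf("InsoleRecording (%s foot): %d samples @ %g Hz, %.2f s\n",
              object@foot, length(object@timeMs), object@samplingRate,
              diff(range(object@timeMs)) / 1000))
  cat(sprintf("  peak pressure %.2f N/cm^2, peak total force %.1f N\n",
              max(object@pressure), max(object@totalForce)))
})

setMethod("show", "GaitProfile", function(object) {
  lab <- paste(na.omit(c(object@groupLabel,
                         if (!is.na(object@medicationState)) object@medicationState,
                         if (!is.na(object@severityLabel)) object@severityLabel)),
               collapse = "/")
  cat(sprintf("GaitProfile [%s, %s]\n", lab, object@testType))
  cat(sprintf("  step duration %.2f s (CV %.2f, L/R %.2f), stance %.1f%%\n",
              object@meanStepDuration, object@stepDurationCV,
              object@asymmetryRatio, 100 * object@stanceFraction))
  cat(sprintf("  step length %.2f m (CV %.2f), distance %g m, noise SD %.2f\n",
              object@meanStepLength, object@stepLengthCV, object@distance,
              object@noiseSD))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d events, %d steps, %.2f m walked, window [%.2f, %.2f] s\n",
    nrow(object@events), length(object@stepLengths), object@distance,
    object@segmentStart, object@segmentEnd))
})

setMethod("show", "DetectorConfig", function(object) {
  cat(sprintf(
    "DetectorConfig: heel {%s}, forefoot {%s}, on %.2f / off %.2f, debounce %g ms\n",
    paste(object@heelChannels, collapse = ","),
    paste(object@forefootChannels, collapse = ","),
    object@onThreshold, object@offThreshold, object@debounceMs))
})

setMethod("show", "BenchReport", function(object) {
  cat(sprintf("BenchReport: task %s, test %s\n", object@task, object@testType))
  cat(sprintf("  features (%d): %s\n", length(object@features),
              paste(object@features, collapse = ", ")))
  print(object@summary, row.names = FALSE)
})
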