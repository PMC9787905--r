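# CSV/JSON artifact formats. Column sets documented in FORMATS.md.

.REC_COLS <- c("time_ms", sprintf("p%02d", 1:16), "ax", "ay", "az",
               "gx", "gy", "gz", "total_force", "cop_x", "cop_y")

.check_schema <- function(found, expected, what) {
  missing <- setdiff(expected, found)
  extra <- setdiff(found, expected)
  if (length(missing) || length(extra))
    stopf("schema error in %s: %s%s", what,
          if (length(missing))
            paste0("missing column(s) ", paste(missing, collapse = ", "))
          else "",
          if (length(extra))
            paste0(if (length(missing)) "; " else "",
                   "unexpected column(s) ", paste(extra, collapse = ", "))
          else "")
  invisible(TRUE)
}

#' Read and write insole recordings
#'
#' Recordings are interchanged as CSV with the fixed column set `time_ms,
#' p01..p16, ax, ay, az, gx, gy, gz, total_force, cop_x, cop_y`. The foot is
#' not stored in the file; it is given at read time (or taken from a
#' `_left`/`_right` suffix of the file name). Round-trips are lossless at
#' the written precision.
#'
#' @param path File path.
#' @param foot `"left"` or `"right"`; default inferred from the file name.
#' @param samplingRate Sampling rate in Hz (default 100).
#' @return `readRecording` returns an [InsoleRecording-class];
#'   `writeRecording` returns `path` invisibly.
#' @examples
#' sim <- simulateRecording(gaitProfile(noiseSD = 0), seed = 1)
#' f <- tempfile(fileext = "_left.csv")
#' writeRecording(sim$left, f)
#' rec <- readRecording(f)
#' @export
readRecording <- function(path, foot = NULL, samplingRate = 100) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- data.table::fread(path, data.table = FALSE)
  .check_schema(names(df), .REC_COLS, path)
  if (is.null(foot)) {
    foot <- if (grepl("left", basename(path))) "left"
      else if (grepl("right", basename(path))) "right"
      else stop("cannot infer foot from file name; pass `foot`",
                call. = FALSE)
  }
  if (any(diff(df$time_ms) <= 0))
    stop("validation error: time_ms not strictly increasing", call. = FALSE)
  insoleRecording(foot, df$time_ms,
                  as.matrix(df[sprintf("p%02d", 1:16)]),
                  accel = as.matrix(df[c("ax", "ay", "az")]),
                  gyro = as.matrix(df[c("gx", "gy", "gz")]),
                  totalForce = df$total_force,
                  cop = as.matrix(df[c("cop_x", "cop_y")]),
                  samplingRate = samplingRate)
}

#' @param rec An [InsoleRecording-class].
#' @rdname readRecording
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "InsoleRecording"))
  df <- data.frame(time_ms = timeMs(rec), pressure(rec), rec@accel,
                   rec@gyro, total_force = totalForce(rec), rec@cop)
  names(df) <- .REC_COLS
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read and write gait event tables
#'
#' Events CSV has columns `foot,event,time_s`; rows are stably sorted into
#' the canonical (foot, time) order on both read and write so round-trips
#' of shuffled tables are reproducible.
#'
#' @param path File path.
#' @return `readEvents` returns the event `data.frame`; `writeEvents`
#'   returns `path` invisibly.
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = c("foot", "event")))
  .check_schema(names(df), c("foot", "event", "time_s"), path)
  if (nrow(df) && !all(df$event %in% gaitEventTypes()))
    stopf("validation error: unknown event type(s): %s",
          paste(setdiff(df$event, gaitEventTypes()), collapse = ", "))
  df <- df[order(df$foot, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @param events Event `data.frame` (columns `foot`, `event`, `time_s`).
#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  .check_schema(names(events), c("foot", "event", "time_s"), "events")
  events <- events[order(events$foot, events$time_s), , drop = FALSE]
  data.table::fwrite(events, path)
  invisible(path)
}

.FEATURE_ID_COLS <- c("participant_id", "group", "medication_state",
                      "severity_level", "test_type", "recording_index")

#' Read and write feature tables
#'
#' Feature CSVs carry exactly the 18 feature columns of
#' [gaitFeatureNames()] plus the identifier columns `participant_id, group,
#' medication_state, severity_level, test_type, recording_index`.
#'
#' @param path File path.
#' @return `readFeatures` returns a `data.frame`; `writeFeatures` returns
#'   `path` invisibly.
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- data.table::fread(path, data.table = FALSE)
  .check_schema(names(df), c(.FEATURE_ID_COLS, gaitFeatureNames()), path)
  df
}

#' @param features Feature `data.frame` with identifier columns.
#' @rdname readFeatures
#' @export
writeFeatures <- function(features, path) {
  .check_schema(names(features), c(.FEATURE_ID_COLS, gaitFeatureNames()),
                "features")
  data.table::fwrite(features[, c(.FEATURE_ID_COLS, gaitFeatureNames())],
                     path)
  invisible(path)
}

#' Read and write session metadata
#'
#' Session metadata is one JSON object per session with the participant,
#' group, medication state, test type, recording index, segment annotation
#' (start/end seconds, nominal and walked distance) and clinical scores.
#' PD sessions must carry a medication state (`ON`, `OFF` or `DCIP`);
#' control sessions carry `NA`.
#'
#' @param path File path.
#' @return `readSessionMetadata` returns a named list;
#'   `writeSessionMetadata` returns `path` invisibly.
#' @export
readSessionMetadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  validateSessionMetadata(meta)
  meta
}

#' @param meta Named list of session metadata.
#' @rdname readSessionMetadata
#' @export
writeSessionMetadata <- function(meta, path) {
  validateSessionMetadata(meta)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname readSessionMetadata
#' @export
validateSessionMetadata <- function(meta) {
  need <- c("participant_id", "group", "test_type")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("validation error: metadata missing field(s) %s",
          paste(miss, collapse = ", "))
  if (!meta$group %in% gaitGroups())
    stopf("validation error: unknown group '%s'", meta$group)
  if (!meta$test_type %in% gaitTestTypes())
    stopf("validation error: unknown test type '%s'", meta$test_type)
  state <- meta$medication_state %||% NA
  if (meta$group == "PD") {
    if (is.null(state) || is.na(state) ||
        !state %in% c("ON", "OFF", "DCIP"))
      stop("validation error: PD sessions carry medication_state ",
           "ON/OFF/DCIP", call. = FALSE)
  } else if (!is.null(state) && !is.na(state)) {
    stop("validation error: medication_state applies to PD sessions only",
         call. = FALSE)
  }
  invisible(TRUE)
}
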