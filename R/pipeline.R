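# End-to-end pipeline: simulate -> detect -> features -> stats -> classify.

#' Run detection and feature extraction over simulated sessions
#'
#' @param sessions Output of [simulateCohort()].
#' @param cfg A [DetectorConfig-class].
#' @return A [GaitSampleTable-class] with one column per session.
#' @examples
#' sessions <- simulateCohort(cohortDesign(nAdults = 2),
#'                            tests = "WST_NORMAL", seed = 1)
#' extractFeatureTable(sessions)
#' @export
extractFeatureTable <- function(sessions, cfg = detectorConfig()) {
  rows <- lapply(sessions, function(s) {
    ev <- detectEvents(s$left, s$right, cfg)
    cyc <- segmentCycles(ev, segmentWindow(s$truth))
    ft <- computeFeatures(cyc, ev, s$distance,
                          window = segmentWindow(s$truth))
    cbind(data.frame(participant_id = s$participant_id, group = s$group,
                     medication_state = s$medication_state,
                     severity_level = s$severity_level,
                     test_type = s$test_type,
                     recording_index = s$recording_index,
                     stringsAsFactors = FALSE),
          ft)
  })
  gaitSampleTable(do.call(rbind, rows))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline from a config file
#'
#' Executes simulate -> detect events -> extract features -> mixed-model
#' screen -> classification bench from a single YAML (or JSON) config,
#' writing every intermediate artifact into a run directory keyed by the
#' config hash, plus a run manifest. Rerunning the same config and seed
#' reproduces every artifact bit-identically.
#'
#' Config fields (all optional except `cohort`): `seed`; `output_dir`;
#' `cohort` (`adults`, `elderly`, `pd`, `pd_dcip`, `pd_states`,
#' `profile_by`); `tests`; `recordings_per_test`; `noise_sd`;
#' `participant_sd`; `detector` (`on_threshold`, `off_threshold`,
#' `debounce_ms`); `stats` (`factors`); `bench` (`tasks`, `classifiers`).
#'
#' @param configPath Path to the YAML/JSON config.
#' @param outputDir Overrides the config's `output_dir` (default: the
#'   config's value, or a `pdgait-run` directory under `tempdir()`).
#' @return The run manifest (named list), invisibly written as
#'   `manifest.json` in the run directory.
#' @export
runAll <- function(configPath, outputDir = NULL) {
  if (!file.exists(configPath)) stopf("config not found: %s", configPath)
  config <- yaml::read_yaml(configPath)
  seed <- config$seed %||% 1L
  hash <- unname(tools::md5sum(configPath))
  outdir <- outputDir %||% config$output_dir %||%
    file.path(tempdir(), "pdgait-run")
  rundir <- file.path(outdir, paste0("run-", substr(hash, 1, 8)))
  for (d in c("recordings", "events", "stats", "bench"))
    dir.create(file.path(rundir, d), recursive = TRUE, showWarnings = FALSE)

  co <- config$cohort %||% stop("config must define a cohort", call. = FALSE)
  tests <- config$tests %||% gaitTestTypes()
  pd_states <- unlist(co$pd_states %||% list("ON", "OFF"))
  if (is.logical(pd_states))           # YAML 1.1 reads bare ON/OFF as booleans
    pd_states <- ifelse(pd_states, "ON", "OFF")
  design <- .stage("design", cohortDesign(
    nAdults = co$adults %||% 0, nElderly = co$elderly %||% 0,
    nPD = co$pd %||% 0, pdDcip = co$pd_dcip %||% 0,
    pdStates = pd_states,
    profileBy = co$profile_by %||% "state"))

  sessions <- .stage("simulate", simulateCohort(
    design, tests = tests,
    recordingsPerTest = config$recordings_per_test %||% 2, seed = seed,
    participantSD = config$participant_sd %||% 1,
    noiseSD = config$noise_sd %||% 0.5))

  det <- config$detector %||% list()
  cfg <- detectorConfig(
    onThreshold = det$on_threshold %||% 0.10,
    offThreshold = det$off_threshold %||% 0.05,
    debounceMs = det$debounce_ms %||% 50)

  n_events <- 0L
  rows <- list()
  .stage("events+features", for (s in sessions) {
    stem <- sprintf("%s_%s_%s_r%d", s$participant_id,
                    ifelse(is.na(s$medication_state), "NA",
                           s$medication_state), s$test_type,
                    s$recording_index)
    writeRecording(s$left, file.path(rundir, "recordings",
                                     paste0(stem, "_left.csv")))
    writeRecording(s$right, file.path(rundir, "recordings",
                                      paste0(stem, "_right.csv")))
    writeEvents(gaitEvents(s$truth),
                file.path(rundir, "recordings", paste0(stem, "_truth.csv")))
    meta <- list(participant_id = s$participant_id, group = s$group,
                 medication_state = s$medication_state,
                 severity_level = s$severity_level,
                 part3_total = s$part3_total,
                 control_subset_total = s$control_subset_total,
                 test_type = s$test_type,
                 recording_index = s$recording_index,
                 segment = list(start_s = segmentWindow(s$truth)[1],
                                end_s = segmentWindow(s$truth)[2],
                                nominal_distance_m = 10,
                                walked_distance_m = s$distance))
    writeSessionMetadata(meta, file.path(rundir, "recordings",
                                         paste0(stem, "_meta.json")))
    ev <- detectEvents(s$left, s$right, cfg)
    n_events <- n_events + nrow(ev)
    writeEvents(ev, file.path(rundir, "events", paste0(stem, ".csv")))
    cyc <- segmentCycles(ev, segmentWindow(s$truth))
    ft <- computeFeatures(cyc, ev, s$distance, segmentWindow(s$truth))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(participant_id = s$participant_id, group = s$group,
                 medication_state = s$medication_state,
                 severity_level = s$severity_level, test_type = s$test_type,
                 recording_index = s$recording_index,
                 stringsAsFactors = FALSE), ft)
  })
  features <- do.call(rbind, rows)
  writeFeatures(features, file.path(rundir, "features.csv"))

  stats_files <- character(0)
  factors <- unlist((config$stats %||% list())$factors %||%
                      list("group"))
  .stage("stats", for (fac in factors) {
    for (tt in tests) {
      res <- tryCatch(lmmScreen(features, fac, testType = tt),
                      error = function(e) NULL)
      if (is.null(res)) next
      f <- file.path(rundir, "stats", sprintf("%s_%s.csv", fac, tt))
      data.table::fwrite(res, f)
      stats_files <- c(stats_files, f)
    }
  })

  bench_files <- character(0)
  bench <- config$bench %||% list()
  tasks <- unlist(bench$tasks %||% list())
  .stage("bench", for (task in tasks) {
    for (tt in tests) {
      bcfg <- benchConfig(
        task, testType = tt,
        classifiers = unlist(bench$classifiers %||%
                               list("adaboost", "extra_trees",
                                    "random_forest")),
        seed = seed)
      rep <- runBench(features, bcfg)
      f <- file.path(rundir, "bench", sprintf("%s_%s.json", task, tt))
      jsonlite::write_json(
        list(task = task, test_type = tt,
             accuracy = setNames(as.list(rep@summary$holdout_accuracy),
                                 rep@summary$classifier),
             cv_mean = setNames(as.list(rep@summary$cv_mean),
                                rep@summary$classifier),
             features = rep@features),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      bench_files <- c(bench_files, f)
    }
  })

  rel <- function(f) sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1",
                                          rundir), "/?"), "", f)
  manifest <- list(
    config_hash = hash, seed = seed,
    package_version = as.character(utils::packageVersion("pdgait")),
    n_sessions = length(sessions), n_events = n_events,
    n_feature_rows = nrow(features),
    stages = list(
      simulate = list(sessions = length(sessions)),
      events = list(files = length(sessions), events = n_events),
      features = list(file = "features.csv", rows = nrow(features)),
      stats = list(files = vapply(stats_files, rel, character(1),
                                  USE.NAMES = FALSE)),
      bench = list(files = vapply(bench_files, rel, character(1),
                                  USE.NAMES = FALSE))))
  jsonlite::write_json(manifest, file.path(rundir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # manifest completeness: every listed file exists
  listed <- c(file.path(rundir, "features.csv"), stats_files, bench_files)
  stopifnot(all(file.exists(listed)))
  invisible(c(manifest, list(run_dir = rundir)))
}
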