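# Gait profiles: published per-condition parameter cells and constructors.

# Per-condition gait parameter cells (means and SDs across recordings) for
# the three participant groups, the two PD medication states and the two
# observed PD severity levels, for each walking test. `left`/`right` are the
# side-specific mean step durations from which the asymmetry ratio derives.
.profile_cells <- local({
  rows <- rbind(
    # test, group, state, severity, dur, dur_sd, left, right, stance_pct, len, len_sd
    # --- group-level cells -------------------------------------------------
    c("WST_SLOW",   "S",  NA, NA, 0.66, 0.09, 0.66, 0.66, 62.74, 0.57, 0.06),
    c("WST_SLOW",   "EL", NA, NA, 0.70, 0.11, 0.69, 0.71, 62.74, 0.57, 0.06),
    c("WST_SLOW",   "PD", NA, NA, 0.68, 0.12, 0.68, 0.69, 63.13, 0.50, 0.13),
    c("WST_NORMAL", "S",  NA, NA, 0.58, 0.06, 0.60, 0.56, 61.84, 0.69, 0.16),
    c("WST_NORMAL", "EL", NA, NA, 0.58, 0.05, 0.58, 0.57, 60.52, 0.66, 0.07),
    c("WST_NORMAL", "PD", NA, NA, 0.60, 0.07, 0.60, 0.60, 61.06, 0.58, 0.14),
    c("WST_HIGH",   "S",  NA, NA, 0.51, 0.08, 0.51, 0.52, 60.87, 0.75, 0.09),
    c("WST_HIGH",   "EL", NA, NA, 0.49, 0.04, 0.49, 0.49, 60.17, 0.76, 0.09),
    c("WST_HIGH",   "PD", NA, NA, 0.55, 0.06, 0.54, 0.55, 59.86, 0.65, 0.17),
    c("MTUG",       "S",  NA, NA, 0.54, 0.05, 0.56, 0.52, 60.65, 0.67, 0.07),
    c("MTUG",       "EL", NA, NA, 0.54, 0.05, 0.53, 0.54, 60.25, 0.67, 0.07),
    c("MTUG",       "PD", NA, NA, 0.57, 0.06, 0.57, 0.56, 60.39, 0.58, 0.13),
    # --- PD medication-state cells ----------------------------------------
    c("WST_SLOW",   "PD", "OFF", NA, 0.71, 0.13, 0.70, 0.71, 63.43, 0.50, 0.14),
    c("WST_SLOW",   "PD", "ON",  NA, 0.66, 0.10, 0.66, 0.66, 62.85, 0.50, 0.13),
    c("WST_NORMAL", "PD", "OFF", NA, 0.61, 0.07, 0.61, 0.61, 61.03, 0.59, 0.16),
    c("WST_NORMAL", "PD", "ON",  NA, 0.59, 0.06, 0.59, 0.59, 61.09, 0.56, 0.12),
    c("WST_HIGH",   "PD", "OFF", NA, 0.55, 0.06, 0.55, 0.55, 59.42, 0.67, 0.19),
    c("WST_HIGH",   "PD", "ON",  NA, 0.54, 0.06, 0.53, 0.55, 60.24, 0.63, 0.15),
    c("MTUG",       "PD", "OFF", NA, 0.57, 0.05, 0.58, 0.56, 59.76, 0.58, 0.11),
    c("MTUG",       "PD", "ON",  NA, 0.57, 0.06, 0.57, 0.56, 60.90, 0.58, 0.14),
    # --- PD severity-level cells ------------------------------------------
    c("WST_SLOW",   "PD", NA, "mild",     0.67, 0.09, 0.67, 0.67, 61.77, 0.57, 0.11),
    c("WST_SLOW",   "PD", NA, "moderate", 0.70, 0.14, 0.69, 0.70, 64.58, 0.43, 0.11),
    c("WST_NORMAL", "PD", NA, "mild",     0.59, 0.05, 0.59, 0.59, 60.76, 0.64, 0.12),
    c("WST_NORMAL", "PD", NA, "moderate", 0.61, 0.08, 0.61, 0.61, 61.41, 0.51, 0.13),
    c("WST_HIGH",   "PD", NA, "mild",     0.55, 0.06, 0.53, 0.56, 60.24, 0.72, 0.16),
    c("WST_HIGH",   "PD", NA, "moderate", 0.55, 0.05, 0.55, 0.54, 59.42, 0.56, 0.14),
    c("MTUG",       "PD", NA, "mild",     0.56, 0.05, 0.56, 0.56, 59.96, 0.64, 0.09),
    c("MTUG",       "PD", NA, "moderate", 0.58, 0.06, 0.59, 0.57, 60.84, 0.51, 0.13))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("test", "group", "state", "severity", "dur", "dur_sd",
                 "left", "right", "stance_pct", "len", "len_sd")
  for (col in c("dur", "dur_sd", "left", "right", "stance_pct", "len", "len_sd"))
    df[[col]] <- as.numeric(df[[col]])
  df
})

#' Construct a gait profile directly
#'
#' The defaults describe textbook normal adult gait: 0.60 s steps (cadence
#' 100 steps/min), a 60/40 stance/swing split, 0.65 m steps over a 10 m
#' straight-line segment, mild step-to-step variability and 0.5 N/cm^2
#' pressure noise. Use [makeProfile()] for the published per-condition cells.
#'
#' @param groupLabel,medicationState,severityLabel,testType Condition labels
#'   (may be `NA` where not applicable).
#' @param meanStepDuration Mean step duration (s).
#' @param stepDurationCV Step-to-step CV of step duration.
#' @param asymmetryRatio Left/right mean step duration ratio.
#' @param stanceFraction Fraction of the gait cycle spent in stance.
#' @param meanStepLength Mean step length (m).
#' @param stepLengthCV Step-to-step CV of step length.
#' @param distance Straight-line distance to walk (m).
#' @param participantSD Between-participant random-effect multiplier (see
#'   [simulateCohort()]); 0 disables participant heterogeneity.
#' @param noiseSD Additive Gaussian pressure noise SD (N/cm^2).
#' @return A [GaitProfile-class].
#' @examples
#' gaitProfile()                      # physiological normal gait
#' gaitProfile(stanceFraction = 0.62) # heavier stance loading
#' @export
gaitProfile <- function(groupLabel = "S", medicationState = NA_character_,
                        severityLabel = NA_character_,
                        testType = "WST_NORMAL",
                        meanStepDuration = 0.60, stepDurationCV = 0.04,
                        asymmetryRatio = 1, stanceFraction = 0.60,
                        meanStepLength = 0.65, stepLengthCV = 0.05,
                        distance = 10, participantSD = 1, noiseSD = 0.5) {
  new("GaitProfile", groupLabel = groupLabel,
      medicationState = as.character(medicationState),
      severityLabel = as.character(severityLabel), testType = testType,
      meanStepDuration = meanStepDuration, stepDurationCV = stepDurationCV,
      asymmetryRatio = asymmetryRatio, stanceFraction = stanceFraction,
      doubleSupportFraction = max(0, 2 * stanceFraction - 1),
      meanStepLength = meanStepLength, stepLengthCV = stepLengthCV,
      distance = distance, participantSD = participantSD, noiseSD = noiseSD)
}

#' Look up the gait profile for a published study condition
#'
#' Returns the generator parameters for one cell of the study's condition
#' grid: participant group (adults S, elderly EL, patients PD) per test, PD
#' medication state (ON/OFF) per test, or PD severity level (mild/moderate)
#' per test. Exactly one of `medicationState` / `severityLabel` may be
#' non-`NA`, and only for the PD group; combinations without a published
#' cell (including severity `normal`/`severe`, for which no recordings
#' exist) raise a configuration error.
#'
#' @param groupLabel `"S"`, `"EL"` or `"PD"`.
#' @param medicationState `"ON"`, `"OFF"` or `NA`.
#' @param severityLabel `"mild"`, `"moderate"` or `NA`.
#' @param testType One of [gaitTestTypes()].
#' @param distance Straight-line distance (m), default 10.
#' @param participantSD,noiseSD See [gaitProfile()].
#' @return A [GaitProfile-class] whose mean step duration, asymmetry, stance
#'   fraction and step length come from the corresponding condition cell.
#' @examples
#' makeProfile("S", testType = "WST_NORMAL")     # 0.58 s steps, 0.69 m
#' makeProfile("PD", medicationState = "OFF", testType = "WST_SLOW")
#' makeProfile("PD", severityLabel = "moderate", testType = "MTUG")
#' @export
makeProfile <- function(groupLabel, medicationState = NA_character_,
                        severityLabel = NA_character_,
                        testType = "WST_NORMAL", distance = 10,
                        participantSD = 1, noiseSD = 0.5) {
  if (!testType %in% gaitTestTypes())
    stopf("configuration error: unknown test type '%s'", testType)
  if (!groupLabel %in% gaitGroups())
    stopf("configuration error: unknown group '%s'", groupLabel)
  state <- as.character(medicationState)
  sev <- as.character(severityLabel)
  if (!is.na(state) && !is.na(sev))
    stop("configuration error: no published cell combines medication state ",
         "and severity level; set exactly one", call. = FALSE)
  if (groupLabel != "PD" && (!is.na(state) || !is.na(sev)))
    stop("configuration error: medication state and severity apply to the ",
         "PD group only", call. = FALSE)
  tab <- .profile_cells
  hit <- tab$test == testType & tab$group == groupLabel &
    (is.na(state) == is.na(tab$state)) &
    (is.na(sev) == is.na(tab$severity))
  if (!is.na(state)) hit <- hit & !is.na(tab$state) & tab$state == state
  if (!is.na(sev)) hit <- hit & !is.na(tab$severity) & tab$severity == sev
  row <- tab[which(hit), , drop = FALSE]
  if (nrow(row) != 1L)
    stopf("configuration error: no profile cell for (%s, %s, %s, %s)",
          groupLabel, state, sev, testType)
  gaitProfile(groupLabel = groupLabel, medicationState = state,
              severityLabel = sev, testType = testType,
              meanStepDuration = row$dur,
              stepDurationCV = row$dur_sd / row$dur,
              asymmetryRatio = row$left / row$right,
              stanceFraction = row$stance_pct / 100,
              meanStepLength = row$len,
              stepLengthCV = row$len_sd / row$len,
              distance = distance, participantSD = participantSD,
              noiseSD = noiseSD)
}
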