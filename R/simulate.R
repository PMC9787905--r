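# Synthetic insole-recording generator with exact ground truth.

# Within-stance placement of foot-flat and heel-rise, as fractions of the
# stance interval. Fixed template constants; only the stance fraction and
# step timing are condition-dependent.
.FF_FRAC <- 0.25
.HR_FRAC <- 0.70
.RAMP_S <- 0.05      # load attack/release time (s)
.LEAD_S <- 0.01      # template lead so the first sample at/after a heel
                     # strike is already loaded (clean zero crossing)
.HEEL_W <- c(1, 0.95, 0.85, 0.75) * 15         # peak N/cm^2, channels 1-4
.MID_W <- c(0.5, 0.8, 1, 0.8, 0.5) * 4         # channels 5-9
.FORE_W <- c(0.7, 0.9, 1, 0.95, 0.85, 0.7, 0.55) * 18  # channels 10-16
.SENSOR_AREA <- 8    # nominal cm^2 per sensor for the total-force channel
.STANCE_PART_SD <- 0.03   # between-participant SD of the stance fraction

# Trapezoidal load pulse active on [on, off): fast attack, plateau, release
# ending exactly at `off`. Shifted by .LEAD_S so samples at/after `on` are
# strictly positive while samples before `on` are exactly zero.
.pulse <- function(t, on, off) {
  act <- t >= on & t < off
  p <- numeric(length(t))
  if (!any(act)) return(p)
  ta <- t[act]
  p[act] <- pmax(0, pmin(1, (ta - on + .LEAD_S) / .RAMP_S,
                         (off - ta) / .RAMP_S))
  p
}

# Smooth mid-stance bump on [on, off).
.bump <- function(t, on, off) {
  act <- t >= on & t < off
  p <- numeric(length(t))
  if (any(act)) p[act] <- sin(pi * (t[act] - on) / (off - on))
  p
}

.foot_pressure <- function(t, ev) {
  # ev: data.frame hs, ff, hr, to (one row per stance episode)
  pres <- matrix(0, length(t), 16)
  for (j in seq_len(nrow(ev))) {
    heel <- .pulse(t, ev$hs[j], ev$hr[j])
    fore <- .pulse(t, ev$ff[j], ev$to[j])
    mid <- .bump(t, ev$ff[j], ev$hr[j])
    pres[, 1:4] <- pres[, 1:4] + outer(heel, .HEEL_W)
    pres[, 5:9] <- pres[, 5:9] + outer(mid, .MID_W)
    pres[, 10:16] <- pres[, 10:16] + outer(fore, .FORE_W)
  }
  pres
}

.build_recording <- function(ft, t, ev, noiseSD, stride_s) {
  pres <- .foot_pressure(t, ev)
  if (noiseSD > 0)
    pres[] <- pmax(0, pres + rnorm(length(pres), 0, noiseSD))
  heel <- rowSums(pres[, 1:4, drop = FALSE])
  mid <- rowSums(pres[, 5:9, drop = FALSE])
  fore <- rowSums(pres[, 10:16, drop = FALSE])
  tot <- heel + mid + fore
  # IMU channels: smooth periodic filler at the stride frequency (format
  # fidelity only; never read downstream).
  ph <- 2 * pi * t / stride_s + if (ft == "left") 0 else pi
  accel <- cbind(0.05 * sin(ph), 0.1 * sin(2 * ph), 1 + 0.15 * cos(ph))
  gyro <- cbind(15 * sin(ph), 40 * cos(ph), 5 * sin(2 * ph))
  cop <- cbind(0.5, ifelse(tot > 0,
                           (0.2 * heel + 0.5 * mid + 0.8 * fore) /
                             pmax(tot, 1e-9), 0.5))
  insoleRecording(ft, round(t * 1000), pres, accel = accel, gyro = gyro,
                  totalForce = tot * .SENSOR_AREA, cop = cop)
}

#' Simulate one bilateral insole recording with ground truth
#'
#' Generates a straight-line walk realising the profile's step durations
#' (with the stated CV and left/right asymmetry), stance fraction and step
#' lengths, emitting 100 Hz per-foot recordings with the full channel set
#' (16 pressures, 3-axis acceleration and angular rate, total force, centre
#' of pressure) plus the exact heel-strike / foot-flat / heel-rise / toe-off
#' event times and true per-step lengths. Pressure waveforms follow a
#' double-bump loading template: heel-region channels load at each heel
#' strike and unload at heel rise, forefoot-region channels load through
#' foot flat and unload at toe off. Walking stops once the cumulative step
#' length reaches the profile distance (so the true walked distance exceeds
#' the nominal distance by less than one step). Identical seed and inputs
#' give bit-identical output.
#'
#' @param profile A [GaitProfile-class].
#' @param participantId Identifier recorded in no channel; reserved for
#'   callers assembling session metadata.
#' @param seed Integer seed; required for reproducibility.
#' @return A list with elements `left` and `right`
#'   ([InsoleRecording-class]) and `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateRecording(gaitProfile(noiseSD = 0), seed = 1)
#' sim$truth
#' @export
simulateRecording <- function(profile, participantId = "P000", seed) {
  validObject(profile)
  with_seed(seed, {
    mT <- profile@meanStepDuration
    a <- profile@asymmetryRatio
    meanL <- 2 * a * mT / (1 + a)   # left step duration (contra HS -> L HS)
    meanR <- 2 * mT / (1 + a)
    s <- profile@stanceFraction
    fs <- 100

    # step lengths until the nominal distance is covered
    lens <- numeric(0)
    while (sum(lens) < profile@distance) {
      if (length(lens) > 10000L)
        stop("simulation error: step lengths fail to cover the distance",
             call. = FALSE)
      lens <- c(lens, rnorm_pos(1, profile@meanStepLength,
                                profile@stepLengthCV * profile@meanStepLength,
                                lower = 0.2 * profile@meanStepLength))
    }
    m <- length(lens)

    # heel strikes: m + 1 events alternating left/right, left first
    feet <- rep(c("left", "right"), length.out = m + 1)
    durs <- vapply(feet[-1], function(ft) {
      mu <- if (ft == "left") meanL else meanR
      rnorm_pos(1, mu, profile@stepDurationCV * mu, lower = 0.3 * mu)
    }, numeric(1))
    hs <- cumsum(c(0.8, durs))

    per_foot <- lapply(c("left", "right"), function(ft) {
      h <- hs[feet == ft]
      stride <- c(diff(h), 2 * mT)
      data.frame(hs = h, ff = h + .FF_FRAC * s * stride,
                 hr = h + .HR_FRAC * s * stride, to = h + s * stride)
    })
    names(per_foot) <- c("left", "right")

    end_t <- max(unlist(lapply(per_foot, function(e) e$to))) + 0.8
    t <- seq(0, end_t, by = 1 / fs)

    left <- .build_recording("left", t, per_foot$left, profile@noiseSD, 2 * mT)
    right <- .build_recording("right", t, per_foot$right, profile@noiseSD, 2 * mT)

    events <- do.call(rbind, lapply(c("left", "right"), function(ft) {
      e <- per_foot[[ft]]
      data.frame(
        foot = ft,
        event = rep(gaitEventTypes(), times = nrow(e)),
        time_s = as.numeric(t(as.matrix(e[, c("hs", "ff", "hr", "to")]))),
        stringsAsFactors = FALSE)
    }))
    events <- events[order(events$foot, events$time_s), ]
    rownames(events) <- NULL

    truth <- new("GroundTruth", events = events, stepLengths = lens,
                 segmentStart = 0, segmentEnd = end_t, distance = sum(lens))
    list(left = left, right = right, truth = truth)
  })
}

#' Describe a simulated cohort
#'
#' @param nAdults,nElderly,nPD Participant counts per group.
#' @param pdStates Medication states recorded for each (non-DCIP) PD
#'   participant; both ON and OFF sessions of one participant share that
#'   participant's random effect.
#' @param pdDcip Number of additional PD participants on a dopamine
#'   continuous-infusion pump (recorded in a single `"DCIP"` state).
#' @param profileBy Which published condition cell drives a PD recording's
#'   gait parameters: the medication `"state"` (default), the `"severity"`
#'   level implied by the participant's MDS-UPDRS Part III score, or the
#'   pooled `"group"` cell. Control groups always use their group cell.
#' @param pdSeverity `"mixed"` (default): PD Part III totals span the mild
#'   and moderate bins; `"mild"` / `"moderate"`: scores are drawn within
#'   that bin only (e.g. for single-severity cohorts).
#' @return A `cohortDesign` list consumed by [simulateCohort()].
#' @export
cohortDesign <- function(nAdults = 0, nElderly = 0, nPD = 0,
                         pdStates = c("ON", "OFF"), pdDcip = 0,
                         profileBy = c("state", "severity", "group"),
                         pdSeverity = c("mixed", "mild", "moderate")) {
  profileBy <- match.arg(profileBy)
  pdSeverity <- match.arg(pdSeverity)
  if (any(c(nAdults, nElderly, nPD, pdDcip) < 0))
    stop("cohort sizes must be >= 0", call. = FALSE)
  if (nAdults + nElderly + nPD + pdDcip < 1)
    stop("cohort must contain at least one participant", call. = FALSE)
  structure(list(nAdults = nAdults, nElderly = nElderly, nPD = nPD,
                 pdStates = pdStates, pdDcip = pdDcip, profileBy = profileBy,
                 pdSeverity = pdSeverity),
            class = "cohortDesign")
}

.clip_score <- function(x, lo = 9, hi = 58) pmin(hi, pmax(lo, round(x)))

#' Simulate a cohort of insole sessions
#'
#' Draws a per-participant random effect (a Gaussian multiplier on the
#' profile's mean step duration and step length, scaled by `participantSD`
#' times the condition cell's CV) so repeated recordings of one participant
#' are correlated, as the repeated-measures mixed model downstream assumes.
#' ON and OFF sessions of a PD participant share the participant effect. PD
#' participants also receive MDS-UPDRS Part III totals (OFF higher than ON)
#' whose [binSeverity()] level is recorded per session; control participants
#' receive Control Subset totals.
#'
#' @param design A [cohortDesign()].
#' @param tests Subset of [gaitTestTypes()] to record.
#' @param recordingsPerTest Recordings per participant, state and test
#'   (default 2, matching the study protocol).
#' @param seed Integer master seed.
#' @param participantSD Between-participant multiplier (0 = homogeneous).
#' @param noiseSD Pressure noise SD (N/cm^2).
#' @param distance Nominal straight-line distance (m).
#' @return List of sessions; each session is a list with the recordings
#'   (`left`, `right`), the `truth`, and metadata fields `participant_id`,
#'   `group`, `medication_state`, `severity_level`, `part3_total`,
#'   `control_subset_total`, `test_type`, `recording_index`, `distance`.
#' @examples
#' sessions <- simulateCohort(cohortDesign(nAdults = 2),
#'                            tests = "WST_NORMAL", seed = 1)
#' length(sessions)
#' @export
simulateCohort <- function(design, tests = gaitTestTypes(),
                           recordingsPerTest = 2, seed = 1,
                           participantSD = 1, noiseSD = 0.5, distance = 10) {
  stopifnot(inherits(design, "cohortDesign"))
  tests <- match.arg(tests, gaitTestTypes(), several.ok = TRUE)
  participants <- with_seed(seed, {
    out <- list()
    add <- function(id, group, states) {
      out[[length(out) + 1L]] <<- list(
        id = id, group = group, states = states,
        eff_dur = rnorm(1), eff_len = rnorm(1), eff_stance = rnorm(1),
        part3 = if (group == "PD") switch(design$pdSeverity,
          mixed = .clip_score(rnorm(1, 36, 15), 9, 58),
          mild = .clip_score(rnorm(1, 20, 6), 9, 32),
          moderate = .clip_score(rnorm(1, 45, 6), 33, 58)) else NA,
        control_subset = if (group == "PD") NA else
          max(0, round(rnorm(1, if (group == "EL") 2 else 0.5, 1))))
      invisible(NULL)
    }
    for (i in seq_len(design$nAdults)) add(sprintf("S%03d", i), "S", NA)
    for (i in seq_len(design$nElderly)) add(sprintf("EL%03d", i), "EL", NA)
    for (i in seq_len(design$nPD))
      add(sprintf("PD%03d", i), "PD", design$pdStates)
    for (i in seq_len(design$pdDcip))
      add(sprintf("PDD%02d", i), "PD", "DCIP")
    out
  })

  sessions <- list()
  counter <- 0L
  for (p in participants) {
    states <- if (all(is.na(p$states))) NA_character_ else p$states
    for (state in states) {
      part3 <- if (p$group == "PD") {
        shift <- switch(state, OFF = 6, ON = -6, 0)
        bounds <- switch(design$pdSeverity, mixed = c(9, 58),
                         mild = c(9, 32), moderate = c(33, 58))
        .clip_score(p$part3 + shift, bounds[1], bounds[2])
      } else NA
      severity <- if (p$group == "PD")
        as.character(binSeverity(part3)) else NA_character_
      for (test in tests) {
        base <- if (p$group != "PD" || design$profileBy == "group") {
          makeProfile(p$group, testType = test, distance = distance,
                      participantSD = participantSD, noiseSD = noiseSD)
        } else if (design$profileBy == "severity") {
          makeProfile("PD", severityLabel = severity, testType = test,
                      distance = distance, participantSD = participantSD,
                      noiseSD = noiseSD)
        } else {
          st <- if (identical(state, "DCIP")) "ON" else state
          makeProfile("PD", medicationState = st, testType = test,
                      distance = distance, participantSD = participantSD,
                      noiseSD = noiseSD)
        }
        # participant random effect: multiplicative shift of the means,
        # scaled by the cell CV so heterogeneity matches the printed spread
        prof <- base
        prof@meanStepDuration <- base@meanStepDuration *
          max(0.4, 1 + participantSD * base@stepDurationCV * p$eff_dur)
        prof@meanStepLength <- base@meanStepLength *
          max(0.4, 1 + participantSD * base@stepLengthCV * p$eff_len)
        # stance fraction carries a participant effect too (the observed
        # stance-phase spread across recordings is about 3 percentage
        # points); clipped to keep double support positive and plausible
        prof@stanceFraction <- min(0.72, max(0.53,
          base@stanceFraction + participantSD * .STANCE_PART_SD *
            p$eff_stance))
        prof@doubleSupportFraction <- 2 * prof@stanceFraction - 1
        for (rec in seq_len(recordingsPerTest)) {
          counter <- counter + 1L
          sim <- simulateRecording(prof, p$id, seed = sub_seed(seed, counter))
          sessions[[length(sessions) + 1L]] <- list(
            participant_id = p$id, group = p$group,
            medication_state = state, severity_level = severity,
            part3_total = part3, control_subset_total = p$control_subset,
            test_type = test, recording_index = rec,
            distance = walkedDistance(sim$truth),
            left = sim$left, right = sim$right, truth = sim$truth)
        }
      }
    }
  }
  sessions
}

#' Simulate a feature-level sample table
#'
#' Draws the 18 gait features directly at the cohort level (participant
#' random intercept plus residual noise, standardised scale) without
#' synthesising waveforms. This is the package's instrument for calibrating
#' the mixed-model screen: type-I error and power studies need hundreds of
#' replicate cohorts, and the screen's input contract is the sample table,
#' not the raw signals.
#'
#' @param design Named integer vector: participants per factor level, e.g.
#'   `c(A = 20, B = 20)`. Level names become the `group` column.
#' @param recordingsPer Recordings per participant (default 2).
#' @param icc Intraclass correlation: share of each feature's unit variance
#'   attributed to the participant intercept.
#' @param effect Optional named numeric vector (names in
#'   [gaitFeatureNames()]): shift added to the named features, in units of
#'   the within-participant (residual) SD, scaled by the level index minus
#'   one (level 1 is the reference).
#' @param seed Integer seed.
#' @return A [GaitSampleTable-class] with `test_type = "WST_NORMAL"`.
#' @examples
#' tab <- simulateFeatureTable(c(A = 5, B = 5), seed = 1)
#' dim(tab)
#' @export
simulateFeatureTable <- function(design, recordingsPer = 2, icc = 0.5,
                                 effect = NULL, seed = 1) {
  stopifnot(length(design) >= 1, !is.null(names(design)), icc >= 0, icc < 1)
  fn <- gaitFeatureNames()
  if (!is.null(effect)) {
    bad <- setdiff(names(effect), fn)
    if (length(bad))
      stopf("unknown feature(s) in effect: %s", paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    n_part <- sum(design)
    lv_of_part <- rep(seq_along(design), times = design)
    n_rows <- n_part * recordingsPer
    part_of_row <- rep(seq_len(n_part), each = recordingsPer)
    intercepts <- matrix(rnorm(n_part * length(fn), 0, sqrt(icc)),
                         n_part, length(fn))
    y <- intercepts[part_of_row, , drop = FALSE] +
      matrix(rnorm(n_rows * length(fn), 0, sqrt(1 - icc)),
             n_rows, length(fn))
    colnames(y) <- fn
    if (!is.null(effect))
      y[, names(effect)] <- y[, names(effect)] +
        outer(lv_of_part[part_of_row] - 1, effect * sqrt(1 - icc))
    df <- data.frame(
      participant_id = sprintf("P%04d", part_of_row),
      group = names(design)[lv_of_part[part_of_row]],
      test_type = "WST_NORMAL", medication_state = NA,
      severity_level = NA,
      recording_index = rep(seq_len(recordingsPer), times = n_part),
      stringsAsFactors = FALSE)
    gaitSampleTable(cbind(df, as.data.frame(y)))
  })
}
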