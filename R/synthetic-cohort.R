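# Synthetic graded-treadmill cohort generator.
#
# Emulates the study design the downstream pipeline expects: six subjects walk
# a graded treadmill protocol (start 4 km/h, +1 km/h per 4-minute stage, seven
# stages), RR intervals are recorded throughout each stage, and at the end of
# each stage the subject reports a Borg 6-20 RPE rating and performs a simple
# reaction time test. Latent fatigue is defined as the fraction of heart-rate
# reserve in use, which makes the ground truth monotone in stage and
# physiologically interpretable.

#' Protocol configuration for the synthetic cohort
#'
#' Defaults encode the graded-treadmill study conditions: 6 subjects, 7
#' four-minute stages starting at 4 km/h with +1 km/h per stage, yielding
#' 42 subject-stage observations.
#'
#' Noise standard deviations control the observation channels: `borg` (RPE
#' units, before rounding to the integer scale), `rt` (ms of reaction time),
#' `hr` (bpm around the stage heart-rate target) and `sdnn` (ms around the
#' stage SDNN target). Setting all to zero gives noiseless, monotone
#' observations.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param nStages number of exercise stages (>= 2).
#' @param stageMinutes duration of each stage in minutes (> 0).
#' @param startSpeed treadmill speed of stage 1, km/h.
#' @param speedIncrement speed increase per stage, km/h.
#' @param seed integer seed; one seeded stream drives the whole cohort.
#' @param noiseSd named list of channel noise standard deviations with entries
#'   `borg`, `rt`, `hr`, `sdnn` (all >= 0).
#' @param profile optional single subject profile (see [subjectProfile()])
#'   applied to every subject instead of randomly drawn profiles; useful when
#'   a deterministic feature-to-index mapping is wanted.
#' @return A validated configuration list of class `ProtocolConfig`.
#' @examples
#' cfg <- protocolConfig(seed = 7)
#' cfg$nSubjects * cfg$nStages
#' @export
protocolConfig <- function(nSubjects = 6, nStages = 7, stageMinutes = 4,
                           startSpeed = 4, speedIncrement = 1, seed = 1,
                           noiseSd = list(borg = 0.6, rt = 10, hr = 2, sdnn = 3),
                           profile = NULL) {
  assertScalarNumber(nSubjects, "nSubjects", lower = 1, integer = TRUE)
  assertScalarNumber(nStages, "nStages", lower = 2, integer = TRUE)
  assertScalarNumber(stageMinutes, "stageMinutes", lower = 1e-9)
  assertScalarNumber(startSpeed, "startSpeed", lower = 0)
  assertScalarNumber(speedIncrement, "speedIncrement", lower = 0)
  assertScalarNumber(seed, "seed", integer = TRUE)
  for (ch in c("borg", "rt", "hr", "sdnn")) {
    if (is.null(noiseSd[[ch]]))
      stop(sprintf("'noiseSd' is missing channel '%s'", ch), call. = FALSE)
    assertScalarNumber(noiseSd[[ch]], paste0("noiseSd$", ch), lower = 0)
  }
  cfg <- list(nSubjects = as.integer(nSubjects), nStages = as.integer(nStages),
              stageMinutes = stageMinutes, startSpeed = startSpeed,
              speedIncrement = speedIncrement, seed = as.integer(seed),
              noiseSd = noiseSd[c("borg", "rt", "hr", "sdnn")], profile = profile)
  class(cfg) <- "ProtocolConfig"
  cfg
}

#' Subject profile for the cohort generator
#'
#' Per-subject physiological parameters. `hrPerKmh` is the heart-rate rise per
#' km/h of treadmill speed above rest; the heart-rate target of stage s at
#' speed v_s is `restingHr + hrPerKmh * (v_s - startSpeed + 1)` (the +1
#' accounts for the onset cost of walking at the initial speed), capped at
#' `maxHr`. Latent fatigue is the heart-rate reserve fraction
#' `(HR - restingHr) / (maxHr - restingHr)`, clipped to \[0, 1\].
#'
#' @param restingHr resting heart rate, bpm (inclusion range 50-90).
#' @param maxHr maximal heart rate, bpm (> restingHr).
#' @param hrPerKmh heart-rate rise per km/h, bpm.
#' @param baselineSdnn resting SDNN, ms; SDNN declines to 15% of baseline at
#'   full fatigue.
#' @param baselineRt rested simple reaction time, ms; reaction time lengthens
#'   by 50% at full fatigue.
#' @return A validated list of class `SubjectProfile`.
#' @export
subjectProfile <- function(restingHr, maxHr, hrPerKmh, baselineSdnn, baselineRt) {
  assertScalarNumber(restingHr, "restingHr", lower = 50, upper = 90)
  assertScalarNumber(maxHr, "maxHr", lower = restingHr + 1e-9)
  assertScalarNumber(hrPerKmh, "hrPerKmh", lower = 0)
  assertScalarNumber(baselineSdnn, "baselineSdnn", lower = 0)
  assertScalarNumber(baselineRt, "baselineRt", lower = 1e-9)
  structure(list(restingHr = restingHr, maxHr = maxHr, hrPerKmh = hrPerKmh,
                 baselineSdnn = baselineSdnn, baselineRt = baselineRt),
            class = "SubjectProfile")
}

# Draw per-subject profiles from the cohort stream. Ranges keep peak-stage
# heart rates below maxHr (no reserve saturation) and RR intervals well inside
# the 300-2000 ms plausibility window.
drawProfiles <- function(config) {
  n <- config$nSubjects
  out <- vector("list", n)
  for (s in seq_len(n)) {
    if (!is.null(config$profile)) { out[[s]] <- config$profile; next }
    restingHr <- stats::runif(1, 60, 70)
    maxHr <- stats::runif(1, 188, 192)
    # fraction of heart-rate reserve consumed per km/h step
    hrPerKmh <- stats::runif(1, 0.10, 0.13) * (maxHr - restingHr)
    out[[s]] <- subjectProfile(restingHr = restingHr, maxHr = maxHr,
                               hrPerKmh = hrPerKmh,
                               baselineSdnn = stats::runif(1, 55, 75),
                               baselineRt = stats::runif(1, 285, 315))
  }
  out
}

#' Simulate one RR-interval series with target HR, SDNN and LF/HF
#'
#' Constructs `RR_k = 60000 / hrTarget` plus a low-frequency sinusoid at
#' 0.10 Hz and a high-frequency sinusoid at 0.25 Hz (the centres of the
#' standard LF and HF bands, so band powers are analytically attributable)
#' plus white jitter. Sinusoid amplitudes are set from `lfHfTarget` with a
#' correction for the broadband jitter power falling in each band, and the
#' jitter is rescaled so the realized standard deviation of the series equals
#' `sdnnTarget` exactly. The modulation is centred, so the series mean equals
#' the target RR.
#'
#' @param hrTarget target mean heart rate, bpm (> 0).
#' @param sdnnTarget target standard deviation of the series, ms (>= 0; 0
#'   gives a constant series).
#' @param lfHfTarget target LF/HF band-power ratio (> 0).
#' @param duration recording length, seconds (>= 60 and long enough for at
#'   least 30 beats).
#' @param seed integer seed for the jitter stream.
#' @param subjectId,stage labels attached to the returned series.
#' @return An [RRISeries-class].
#' @examples
#' rri <- simulateRR(80, 40, 4, duration = 240, seed = 1)
#' 60000 / mean(rrIntervals(rri))
#' @export
simulateRR <- function(hrTarget, sdnnTarget, lfHfTarget = 1, duration = 240,
                       seed = 1, subjectId = NA_character_, stage = NA_integer_) {
  assertScalarNumber(hrTarget, "hrTarget", lower = 1e-9)
  assertScalarNumber(sdnnTarget, "sdnnTarget", lower = 0)
  assertScalarNumber(lfHfTarget, "lfHfTarget", lower = 1e-9)
  assertScalarNumber(duration, "duration", lower = 60)
  base <- 60000 / hrTarget
  n <- floor(duration * 1000 / base)
  if (n < 30)
    stop(sprintf("duration %.1f s holds only %d beats at %.0f bpm; need >= 30",
                 duration, n, hrTarget), call. = FALSE)
  if (sdnnTarget == 0)
    return(RRISeries(rep(base, n), subjectId = subjectId, stage = stage))

  # nominal beat grid; evaluating the modulation at nominal beat times keeps
  # the band attribution exact
  tt <- (seq_len(n) - 1) * base / 1000
  sinFrac <- 0.9
  vSin <- sinFrac * sdnnTarget^2
  varJ <- (1 - sinFrac) * sdnnTarget^2
  # expected white-jitter power landing in each analysis band (jitter is white
  # up to the beat Nyquist frequency)
  fNyqBeat <- (hrTarget / 60) / 2
  psdJ <- varJ / fNyqBeat
  jLf <- psdJ * 0.11
  jHf <- psdJ * min(0.25, max(0, fNyqBeat - 0.15))
  hfVar <- max(0, (vSin - lfHfTarget * jHf + jLf) / (1 + lfHfTarget))
  lfVar <- vSin - hfVar
  s <- sqrt(2 * max(0, lfVar)) * sin(2 * pi * 0.10 * tt) +
       sqrt(2 * hfVar) * sin(2 * pi * 0.25 * tt + 1)
  s <- s - mean(s)
  j <- withLocalSeed(seed, stats::rnorm(n))
  j <- j - mean(j)
  j <- j / stats::sd(j)
  # scale jitter so sd(s + c j) = sdnnTarget exactly
  cv <- sum(s * j) / (n - 1)
  vs <- stats::var(s)
  disc <- cv^2 - (vs - sdnnTarget^2)
  cj <- if (disc > 0) -cv + sqrt(disc) else 0
  rr <- base + s + cj * j
  # physiological plausibility floor/ceiling of the generator
  rr <- pmin(pmax(rr, 310), 1990)
  RRISeries(rr, subjectId = subjectId, stage = stage)
}

#' Simulate a full graded-treadmill cohort
#'
#' Draws subject profiles first, then, per subject-stage, a stage heart-rate
#' and SDNN target (latent fatigue = heart-rate reserve fraction), an
#' RR-interval series via [simulateRR()], an integer Borg 6-20 rating rising
#' with fatigue, and a simple reaction time lengthening by 50% of baseline at
#' full fatigue. Identical seeds reproduce identical cohorts; per-series
#' jitter seeds are derived deterministically from the cohort seed, so subject
#' s / stage t is reproducible even when `nStages` changes.
#'
#' @param config a [protocolConfig()].
#' @return A [FatigueCohort-class] with one series and one observation row per
#'   subject-stage.
#' @examples
#' cohort <- simulateCohort(protocolConfig(seed = 1))
#' nrow(observations(cohort))
#' @export
simulateCohort <- function(config = protocolConfig()) {
  if (!inherits(config, "ProtocolConfig"))
    stop("'config' must come from protocolConfig()", call. = FALSE)
  withLocalSeed(config$seed, {
    profiles <- drawProfiles(config)
    ns <- config$nSubjects
    nt <- config$nStages
    series <- vector("list", ns * nt)
    obs <- vector("list", ns * nt)
    for (s in seq_len(ns)) {
      pr <- profiles[[s]]
      hrr <- pr$maxHr - pr$restingHr
      for (t in seq_len(nt)) {
        speed <- config$startSpeed + (t - 1) * config$speedIncrement
        hrDet <- min(pr$maxHr,
                     pr$restingHr + pr$hrPerKmh * (speed - config$startSpeed + 1))
        tf <- min(1, max(0, (hrDet - pr$restingHr) / hrr))
        hrTarget <- min(pr$maxHr, max(40, hrDet + stats::rnorm(1, 0, config$noiseSd$hr)))
        sdnnTarget <- max(5, pr$baselineSdnn * (1 - 0.85 * tf) +
                             stats::rnorm(1, 0, config$noiseSd$sdnn))
        idx <- (s - 1) * nt + t
        series[[idx]] <- simulateRR(hrTarget, sdnnTarget,
                                    lfHfTarget = 1 + 4 * tf,
                                    duration = config$stageMinutes * 60,
                                    seed = deriveSeed(config$seed, s, t),
                                    subjectId = sprintf("subj%d", s), stage = t)
        borg <- min(20, max(6, round(6 + 14 * tf +
                                     stats::rnorm(1, 0, config$noiseSd$borg))))
        rt <- pr$baselineRt * (1 + 0.5 * tf) + stats::rnorm(1, 0, config$noiseSd$rt)
        obs[[idx]] <- data.frame(subject = sprintf("subj%d", s), stage = t,
                                 speed_kmh = speed, borg = as.integer(borg),
                                 rt_ms = rt, true_fatigue = tf)
      }
    }
    profDf <- do.call(rbind, lapply(seq_along(profiles), function(i)
      data.frame(subject = sprintf("subj%d", i),
                 as.data.frame(unclass(profiles[[i]])))))
    new("FatigueCohort", series = series, observations = do.call(rbind, obs),
        profiles = profDf, config = unclass(config))
  })
}

#' Write a cohort to disk
#'
#' Writes one `.rr` text file per subject-stage (one interval in ms per line,
#' named `subj{S}_stage{T}.rr`) plus `observations.csv`.
#'
#' @param cohort a [FatigueCohort-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "FatigueCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort@series, function(s) {
    p <- file.path(dir, sprintf("subj%s_stage%d.rr",
                                sub("^subj", "", s@subjectId), s@stage))
    writeRRI(s, p)
    p
  }, character(1))
  obsPath <- file.path(dir, "observations.csv")
  utils::write.csv(format(cohort@observations, digits = 15, trim = TRUE),
                   obsPath, row.names = FALSE, quote = FALSE)
  invisible(c(paths, obsPath))
}
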