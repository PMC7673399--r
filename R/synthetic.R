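#' @include gait-pipeline.R eeg-pipeline.R
NULL

#' Simulation parameters for synthetic gait
#'
#' Group effects are placed on the variables known to separate patients from
#' controls: walking speed, cadence and stride, plus a reduced right-arm
#' swing in the patient groups (so that the lower-body + right-upper-limb
#' key-point subset is the most informative subset in simulation). At
#' `effectSize = 1` the group means are typical clinic values (HC about
#' 1.1 m/s and 1.9 steps/s; AD markedly slower); `effectSize = 0` makes all
#' three groups kinematically identical (null configuration).
#'
#' @param effectSize scalar in `[0, 1]`-ish scaling the HC-patient gaps.
#' @param frameRate sensor frame rate, Hz (default 30).
#' @param framesPerRecord frames per walking record (default 180, a 6 s
#'   front-view pass).
#' @param jointNoiseSd additive per-coordinate noise sd in meters.
#' @param cameraTiltDeg ceiling-mount camera tilt in degrees; records are
#'   produced in the tilted camera frame so the rotation step of the
#'   preprocessing is exercised.
#' @param groups optional full per-group override: a named list
#'   (`HC`,`MCI`,`AD`) of lists with `speedMean`, `speedSd`, `cadenceMean`,
#'   `cadenceSd`, `strideMean`, `strideSd`, `rightArmFactor`.
#' @return list of class `"gaitSimParams"`.
#' @export
gaitSimParams <- function(effectSize = 1, frameRate = 30,
                          framesPerRecord = 180L, jointNoiseSd = 0.01,
                          cameraTiltDeg = 27, groups = NULL) {
  if (is.null(groups)) {
    base <- list(speedMean = 1.10, speedSd = 0.07,
                 cadenceMean = 1.90, cadenceSd = 0.08,
                 strideMean = 0.60, strideSd = 0.04,
                 rightArmFactor = 1.0)
    gap <- list(MCI = c(speed = 0.25, cadence = 0.30, stride = 0.18,
                        arm = 0.55),
                AD = c(speed = 0.45, cadence = 0.55, stride = 0.30,
                       arm = 0.70))
    mk <- function(g) {
      p <- base
      p$speedMean <- base$speedMean - effectSize * g[["speed"]]
      p$cadenceMean <- base$cadenceMean - effectSize * g[["cadence"]]
      p$strideMean <- base$strideMean - effectSize * g[["stride"]]
      p$rightArmFactor <- 1 - effectSize * g[["arm"]]
      p
    }
    groups <- list(HC = base, MCI = mk(gap$MCI), AD = mk(gap$AD))
  }
  structure(list(effectSize = effectSize, frameRate = frameRate,
                 framesPerRecord = as.integer(framesPerRecord),
                 jointNoiseSd = jointNoiseSd,
                 cameraTiltDeg = cameraTiltDeg, groups = groups),
            class = "gaitSimParams")
}

# Standing template pose, meters; x right, y up, z depth (away from camera).
kinectTemplatePose <- function() {
  m <- rbind(
    c(0.00, 0.95, 0), c(0.00, 1.20, 0), c(0.00, 1.45, 0), c(0.00, 1.60, 0),
    c(-0.18, 1.40, 0), c(-0.22, 1.15, 0), c(-0.24, 0.92, 0), c(-0.25, 0.85, 0),
    c(0.18, 1.40, 0), c(0.22, 1.15, 0), c(0.24, 0.92, 0), c(0.25, 0.85, 0),
    c(-0.09, 0.90, 0), c(-0.10, 0.50, 0), c(-0.11, 0.10, 0), c(-0.11, 0.03, 0.12),
    c(0.09, 0.90, 0), c(0.10, 0.50, 0), c(0.11, 0.10, 0), c(0.11, 0.03, 0.12),
    c(0.00, 1.38, 0), c(-0.26, 0.78, 0), c(-0.22, 0.82, 0),
    c(0.26, 0.78, 0), c(0.22, 0.82, 0))
  t(m)  # 3 x 25
}

#' Generate one synthetic walking record
#'
#' A 25-joint skeleton walks toward the camera: the pelvis translates at the
#' subject's sampled speed; legs and arms follow sinusoidal flexion
#' trajectories at half the sampled cadence (one cycle per stride),
#' left/right in antiphase, with per-step ankle lift and a small trunk bob;
#' the right-arm swing is scaled by the group's `rightArmFactor`. The whole
#' scene is expressed in the tilted camera frame and iid Gaussian
#' coordinate noise is added. Pure function of its seed.
#'
#' @param params a [gaitSimParams()] list.
#' @param group `"HC"`, `"MCI"` or `"AD"`.
#' @param subjectId identifier for the record.
#' @param seed integer seed.
#' @return a front-view [SkeletonRecord-class].
#' @export
generateGaitRecord <- function(params, group, subjectId = group,
                               seed = 1L) {
  g <- params$groups[[group]]
  if (is.null(g)) stop("unknown group: ", group)
  withSeed(seed, {
    speed <- max(0, stats::rnorm(1, g$speedMean, g$speedSd))
    cadence <- max(0.05, stats::rnorm(1, g$cadenceMean, g$cadenceSd))
    stride <- max(0, stats::rnorm(1, g$strideMean, g$strideSd))
    armF <- c(left = 1, right = max(0, g$rightArmFactor))
    tN <- params$framesPerRecord
    tt <- (seq_len(tN) - 1L) / params$frameRate
    f <- cadence / 2                      # leg cycle frequency
    phL <- 2 * pi * f * tt
    phR <- phL + pi
    base <- kinectTemplatePose()
    x <- array(base, c(3L, 25L, tN))
    # pelvis translation toward the camera (z decreasing)
    x[3L, , ] <- x[3L, , ] + rep(4.5 - speed * tt, each = 25L)
    sAmp <- stride / 2
    lift <- 0.08 * (stride / 0.6)
    bob <- 0.015 * (stride / 0.6)
    addZ <- function(j, amp, ph) x[3L, j, ] <<- x[3L, j, ] + amp * sin(ph)
    addY <- function(j, amp, ph)
      x[2L, j, ] <<- x[2L, j, ] + amp * (1 - cos(ph)) / 2
    legs <- list(list(hip = 13L, knee = 14L, ankle = 15L, foot = 16L,
                      ph = phL),
                 list(hip = 17L, knee = 18L, ankle = 19L, foot = 20L,
                      ph = phR))
    for (leg in legs) {
      addZ(leg$hip, 0.15 * sAmp, leg$ph)
      addZ(leg$knee, 0.5 * sAmp, leg$ph)
      addZ(leg$ankle, sAmp, leg$ph)
      addZ(leg$foot, sAmp, leg$ph)
      addY(leg$knee, 0.4 * lift, leg$ph)
      addY(leg$ankle, lift, leg$ph)
      addY(leg$foot, lift, leg$ph)
    }
    # arms swing in antiphase with the ipsilateral leg
    arms <- list(list(sh = 5L, el = 6L, wr = 7L, ha = 8L, tip = 22L,
                      th = 23L, ph = phR, f = armF[["left"]]),
                 list(sh = 9L, el = 10L, wr = 11L, ha = 12L, tip = 24L,
                      th = 25L, ph = phL, f = armF[["right"]]))
    for (arm in arms) {
      amp <- 0.25 * stride * arm$f
      addZ(arm$sh, 0.15 * amp, arm$ph)
      addZ(arm$el, 0.6 * amp, arm$ph)
      for (j in c(arm$wr, arm$ha, arm$tip, arm$th)) addZ(j, amp, arm$ph)
    }
    # trunk bob at step rate (two steps per leg cycle)
    for (j in c(1L, 2L, 3L, 4L, 21L))
      addY(j, bob, 2 * (phL))
    # express in the tilted camera frame
    r <- rotationMatrixX(params$cameraTiltDeg)
    m <- r %*% matrix(x, 3L)
    if (params$jointNoiseSd > 0)
      m <- m + stats::rnorm(length(m), sd = params$jointNoiseSd)
    dim(m) <- c(3L, 25L, tN)
    skeletonRecord(subjectId, m, view = "front")
  })
}

#' Simulation parameters for synthetic resting EEG
#'
#' Emulates resting EEG as band-limited oscillators (theta 4-8 Hz, alpha
#' 8-12 Hz, beta 13-30 Hz) spatially mixed across the 62 scalp channels
#' plus 1/f background noise, with group-dependent band amplitudes:
#' relative to MCI, AD has higher theta and lower alpha amplitude (the EEG
#' slowing signature). The alpha amplitude is boosted in the eyes-closed
#' condition. `effectSize = 1` gives a large group-mean separation relative
#' to the between-subject spread (EEG slowing between MCI and AD is a large
#' group-level effect), while epoch-to-epoch variability keeps single-epoch
#' discrimination moderate; `effectSize = 0` makes the groups identical.
#'
#' @param effectSize scalar scaling the AD-vs-MCI band-amplitude gaps.
#' @param samplingRate acquisition sampling rate in Hz (default 500 for
#'   desk-scale work; set 5000 for the full acquisition geometry).
#' @param duration seconds per condition (default 60; the full protocol is
#'   480 s = 8 min).
#' @param backgroundExponent spectral exponent of the 1/f background.
#' @param backgroundRms background noise rms in microvolts.
#' @param alphaClosedBoost multiplicative alpha boost with eyes closed.
#' @param nSourcesPerBand number of spatial sources per band.
#' @param mixingSeed seed fixing the source-to-channel topography (shared
#'   by all subjects).
#' @param groups optional per-group override: named list (`MCI`, `AD`) of
#'   lists with `thetaMean`, `thetaSd`, `alphaMean`, `alphaSd`, `betaMean`,
#'   `betaSd` (amplitudes in microvolts).
#' @return list of class `"eegSimParams"`.
#' @export
eegSimParams <- function(effectSize = 1, samplingRate = 500,
                         duration = 60, backgroundExponent = 1,
                         backgroundRms = 4, alphaClosedBoost = 1.8,
                         nSourcesPerBand = 3L, mixingSeed = 42L,
                         groups = NULL) {
  if (is.null(groups)) {
    mci <- list(thetaMean = 4.0, thetaSd = 0.5,
                alphaMean = 7.0, alphaSd = 0.7,
                betaMean = 2.5, betaSd = 0.3)
    ad <- mci
    ad$thetaMean <- mci$thetaMean + effectSize * 2.5
    ad$alphaMean <- max(0, mci$alphaMean - effectSize * 3.0)
    ad$betaMean <- max(0, mci$betaMean - effectSize * 0.5)
    groups <- list(MCI = mci, AD = ad)
  }
  structure(list(effectSize = effectSize, samplingRate = samplingRate,
                 duration = duration,
                 backgroundExponent = backgroundExponent,
                 backgroundRms = backgroundRms,
                 alphaClosedBoost = alphaClosedBoost,
                 nSourcesPerBand = as.integer(nSourcesPerBand),
                 mixingSeed = as.integer(mixingSeed),
                 bands = list(theta = c(4, 8), alpha = c(8, 12),
                              beta = c(13, 30)),
                 groups = groups),
            class = "eegSimParams")
}

# Band-limited unit-variance noise columns via spectral masking
# (one mvfft call for all columns).
bandNoise <- function(n, fs, band, ncols = 1L) {
  w <- matrix(stats::rnorm(n * ncols), n, ncols)
  sp <- stats::mvfft(w)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)              # two-sided frequency axis
  sp[freq < band[1] | freq > band[2], ] <- 0
  x <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  s <- apply(x, 2L, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}

onePerFNoise <- function(n, fs, exponent, ncols = 1L) {
  w <- matrix(stats::rnorm(n * ncols), n, ncols)
  sp <- stats::mvfft(w)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  shape <- c(0, (freq[-1])^(-exponent / 2))
  x <- Re(stats::mvfft(sp * shape, inverse = TRUE)) / n
  sweep(x, 2L, apply(x, 2L, stats::sd), "/")
}

#' Generate one synthetic resting EEG recording
#'
#' 64 labelled channels at the configured sampling rate: the 62 scalp
#' channels carry the mixed band-limited sources plus 1/f background noise;
#' the `Ref` and `Gnd` channels are flat. Subject band amplitudes are drawn
#' once from the group distribution using `seed`, so the two conditions of
#' a subject share amplitudes when called with the same seed. Pure function
#' of its seed.
#'
#' @param params an [eegSimParams()] list.
#' @param group `"MCI"` or `"AD"`.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param subjectId identifier.
#' @param seed integer seed (same value for both conditions of a subject).
#' @return an [EEGRecord-class] with 64 channels.
#' @export
generateEEGRecord <- function(params, group,
                              condition = c("eyes_open", "eyes_closed"),
                              subjectId = group, seed = 1L) {
  condition <- match.arg(condition)
  g <- params$groups[[group]]
  if (is.null(g)) stop("unknown group: ", group)
  labels <- eegChannelLabels64()
  scalp <- which(!labels %in% c("Ref", "Gnd"))
  nCh <- length(scalp)
  n <- as.integer(round(params$duration * params$samplingRate))
  nb <- length(params$bands)
  ns <- params$nSourcesPerBand
  # fixed topography across subjects
  mix <- withSeed(params$mixingSeed,
                  lapply(seq_len(nb), function(b)
                    matrix(stats::rnorm(nCh * ns, sd = 1 / sqrt(ns)),
                           nCh, ns)))
  amps <- withSeed(seed, c(
    theta = max(0, stats::rnorm(1, g$thetaMean, g$thetaSd)),
    alpha = max(0, stats::rnorm(1, g$alphaMean, g$alphaSd)),
    beta = max(0, stats::rnorm(1, g$betaMean, g$betaSd))))
  if (condition == "eyes_closed")
    amps[["alpha"]] <- amps[["alpha"]] * params$alphaClosedBoost
  signalSeed <- (seed + if (condition == "eyes_closed") 499979L else 0L) %%
    2147483647L
  data <- withSeed(signalSeed, {
    out <- matrix(0, nCh, n)
    for (b in seq_len(nb)) {
      src <- bandNoise(n, params$samplingRate, params$bands[[b]], ns)
      out <- out + amps[[b]] * (mix[[b]] %*% t(src))
    }
    out + params$backgroundRms *
      t(onePerFNoise(n, params$samplingRate, params$backgroundExponent,
                     nCh))
  })
  full <- matrix(0, length(labels), n)
  full[scalp, ] <- data
  eegRecord(subjectId, full, params$samplingRate, condition, labels)
}

#' Generate a full synthetic cohort
#'
#' HC subjects carry gait data only; MCI and AD subjects carry gait plus
#' both EEG conditions, mirroring the study design in which EEG is not
#' collected from controls. Regeneration with the same master seed
#' reproduces the cohort (and its manifest) exactly.
#'
#' @param gaitParams a [gaitSimParams()] list.
#' @param eegParams an [eegSimParams()] list.
#' @param sizes named integer vector `c(HC=, MCI=, AD=)`.
#' @param seed master seed.
#' @return a [Cohort-class].
#' @export
#' @examples
#' co <- generateCohort(gaitSimParams(framesPerRecord = 70),
#'                      eegSimParams(duration = 3),
#'                      sizes = c(HC = 1, MCI = 1, AD = 1), seed = 1)
generateCohort <- function(gaitParams = gaitSimParams(),
                           eegParams = eegSimParams(),
                           sizes = c(HC = 35L, MCI = 35L, AD = 17L),
                           seed = 1L) {
  stopifnot(all(sizes >= 1L))
  subjects <- list()
  rows <- list()
  k <- 0L
  for (grp in names(sizes)) {
    for (i in seq_len(sizes[[grp]])) {
      k <- k + 1L
      id <- sprintf("%s%03d", grp, i)
      sseed <- (seed + 104729L * k) %% 2147483647L
      gait <- generateGaitRecord(gaitParams, grp, id, seed = sseed)
      hasEeg <- grp %in% c("MCI", "AD")
      eo <- ec <- NULL
      if (hasEeg) {
        eo <- generateEEGRecord(eegParams, grp, "eyes_open", id,
                                seed = sseed)
        ec <- generateEEGRecord(eegParams, grp, "eyes_closed", id,
                                seed = sseed)
      }
      subjects[[k]] <- methods::new("SubjectRecord", subjectId = id,
                                    label = grp, gait = gait,
                                    eegOpen = eo, eegClosed = ec)
      rows[[k]] <- data.frame(subject_id = id, label = grp,
                              has_eeg = hasEeg)
    }
  }
  methods::new("Cohort", subjects = subjects,
               manifest = do.call(rbind, rows))
}
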