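test_that("gait generation is a pure function of its seed", {
  p <- gaitSimParams(framesPerRecord = 40L)
  r1 <- generateGaitRecord(p, "MCI", "m1", seed = 7)
  r2 <- generateGaitRecord(p, "MCI", "m1", seed = 7)
  expect_identical(r1@coords, r2@coords)
  r3 <- generateGaitRecord(p, "MCI", "m1", seed = 8)
  expect_false(identical(r1@coords, r3@coords))
  expect_equal(nFrames(r1), 40L)
  expect_equal(nJoints(r1), 25L)
})

test_that("zero speed, amplitude and noise give a static skeleton", {
  p <- gaitSimParams(framesPerRecord = 30L, jointNoiseSd = 0)
  p$groups$HC$speedMean <- 0; p$groups$HC$speedSd <- 0
  p$groups$HC$strideMean <- 0; p$groups$HC$strideSd <- 0
  rec <- generateGaitRecord(p, "HC", seed = 1)
  ref <- rec@coords[, , 1]
  for (f in seq_len(nFrames(rec)))
    expect_equal(rec@coords[, , f], ref)
})

test_that("the ankle periodogram peaks at the leg cycle frequency", {
  p <- gaitSimParams(framesPerRecord = 300L, jointNoiseSd = 0)
  rec <- generateGaitRecord(p, "HC", seed = 5)
  # undo the camera tilt, then inspect the left ankle's vertical track
  flat <- rotateRecord(rec, -p$cameraTiltDeg)
  y <- flat@coords[2, 15, ]
  sp <- stats::spec.pgram(ts(y - mean(y), frequency = p$frameRate),
                          plot = FALSE, taper = 0, detrend = FALSE)
  peak <- sp$freq[which.max(sp$spec)]
  # recover the cadence the generator sampled for this seed
  cad <- adcascade:::withSeed(5, {
    speed <- max(0, rnorm(1, p$groups$HC$speedMean, p$groups$HC$speedSd))
    max(0.05, rnorm(1, p$groups$HC$cadenceMean, p$groups$HC$cadenceSd))
  })
  bin <- p$frameRate / 300
  expect_lt(abs(peak - cad / 2), bin + 1e-9)
})

test_that("eeg generation is seeded and silent channels stay flat", {
  p <- eegSimParams(samplingRate = 250, duration = 2)
  r1 <- generateEEGRecord(p, "AD", "eyes_open", "a", seed = 3)
  r2 <- generateEEGRecord(p, "AD", "eyes_open", "a", seed = 3)
  expect_identical(r1@data, r2@data)
  expect_equal(nrow(r1@data), 64L)
  ref <- which(r1@channelLabels %in% c("Ref", "Gnd"))
  expect_true(all(r1@data[ref, ] == 0))
  # zero band amplitudes and zero background give all-zero channels
  p0 <- eegSimParams(samplingRate = 250, duration = 1, backgroundRms = 0)
  for (g in names(p0$groups)) {
    p0$groups[[g]][c("thetaMean", "alphaMean", "betaMean")] <- 0
    p0$groups[[g]][c("thetaSd", "alphaSd", "betaSd")] <- 0
  }
  z <- generateEEGRecord(p0, "MCI", "eyes_open", "m", seed = 1)
  expect_true(all(z@data == 0))
})

test_that("AD records carry more theta power than MCI records", {
  p <- eegSimParams(samplingRate = 250, duration = 4)
  bandPowerOracle <- function(rec, band) {
    x <- rec@data[10, ]                     # one scalp channel
    sp <- stats::spec.pgram(ts(x, frequency = rec@samplingRate),
                            plot = FALSE, taper = 0)
    mean(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
  }
  nSub <- 30
  theta <- sapply(seq_len(nSub), function(i) {
    c(mci = bandPowerOracle(generateEEGRecord(p, "MCI", "eyes_open",
                                              "m", seed = 100 + i),
                            c(4, 8)),
      ad = bandPowerOracle(generateEEGRecord(p, "AD", "eyes_open",
                                             "a", seed = 200 + i),
                           c(4, 8)))
  })
  expect_gt(mean(theta["ad", ]), mean(theta["mci", ]))
  # and the alpha relation reverses (slowing)
  alpha <- sapply(seq_len(10), function(i) {
    c(mci = bandPowerOracle(generateEEGRecord(p, "MCI", "eyes_open",
                                              "m", seed = 100 + i),
                            c(8, 12)),
      ad = bandPowerOracle(generateEEGRecord(p, "AD", "eyes_open",
                                             "a", seed = 200 + i),
                           c(8, 12)))
  })
  expect_lt(mean(alpha["ad", ]), mean(alpha["mci", ]))
})

test_that("eyes-closed boosts alpha for the same subject seed", {
  p <- eegSimParams(samplingRate = 250, duration = 4)
  power <- function(cond) {
    rec <- generateEEGRecord(p, "MCI", cond, "m", seed = 11)
    x <- rec@data[10, ]
    sp <- stats::spec.pgram(ts(x, frequency = 250), plot = FALSE,
                            taper = 0)
    mean(sp$spec[sp$freq >= 8 & sp$freq <= 12])
  }
  expect_gt(power("eyes_closed"), power("eyes_open"))
})

test_that("cohorts mirror the study design and reproduce exactly", {
  gp <- gaitSimParams(framesPerRecord = 30L)
  ep <- eegSimParams(samplingRate = 250, duration = 1)
  co <- generateCohort(gp, ep, sizes = c(HC = 1L, MCI = 1L, AD = 1L),
                       seed = 2)
  expect_length(co@subjects, 3L)
  expect_equal(sum(co@manifest$has_eeg), 2L)
  expect_null(co@subjects[[1]]@eegOpen)           # HC: gait only
  expect_false(is.null(co@subjects[[2]]@eegOpen)) # MCI: both modalities
  expect_false(is.null(co@subjects[[2]]@eegClosed))
  co2 <- generateCohort(gp, ep, sizes = c(HC = 1L, MCI = 1L, AD = 1L),
                        seed = 2)
  expect_identical(co@manifest, co2@manifest)
  expect_identical(co@subjects[[3]]@gait@coords,
                   co2@subjects[[3]]@gait@coords)
  # the full study geometry: 35 + 35 + 17 subjects, 52 with EEG
  co3 <- generateCohort(gp, eegSimParams(samplingRate = 250,
                                         duration = 0.5),
                        sizes = c(HC = 35L, MCI = 35L, AD = 17L), seed = 3)
  expect_length(co3@subjects, 87L)
  expect_equal(sum(co3@manifest$has_eeg), 52L)
})

test_that("zero effect size makes the groups exchangeable in distribution", {
  g0 <- gaitSimParams(effectSize = 0)
  expect_identical(g0$groups$HC, g0$groups$MCI)
  expect_identical(g0$groups$HC, g0$groups$AD)
  e0 <- eegSimParams(effectSize = 0)
  expect_identical(e0$groups$MCI, e0$groups$AD)
  # and the default direction of the effects is the slowing signature
  e1 <- eegSimParams()
  expect_gt(e1$groups$AD$thetaMean, e1$groups$MCI$thetaMean)
  expect_lt(e1$groups$AD$alphaMean, e1$groups$MCI$alphaMean)
  g1 <- gaitSimParams()
  expect_gt(g1$groups$HC$speedMean, g1$groups$MCI$speedMean)
  expect_gt(g1$groups$MCI$speedMean, g1$groups$AD$speedMean)
})
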