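scoresFor <- function(k, n, classes = 2) {
  # k items voting for class 2, the rest for class 1, margins 0.8/0.2
  s <- matrix(0.8, 2, n)
  s[2, ] <- 0.2
  if (k > 0) {
    s[1, seq_len(k)] <- 0.2
    s[2, seq_len(k)] <- 0.8
  }
  s
}

test_that("stage-1 voting applies the strict majority rule", {
  v <- voteStage1(scoresFor(12, 20))
  expect_equal(v$patientFraction, 0.6)
  expect_equal(v$decision, "PATIENT")
  expect_equal(voteStage1(scoresFor(10, 20))$decision, "HC")  # not > 50%
  expect_equal(voteStage1(scoresFor(0, 7))$decision, "HC")
  expect_error(voteStage1(matrix(0, 2, 0)), "at least one clip")
})

test_that("stage-2 voting applies majority with the summed-score tie rule", {
  expect_equal(voteStage2(scoresFor(80, 120))$decision, "AD")
  expect_equal(voteStage2(scoresFor(120, 120))$adFraction, 1)
  expect_equal(voteStage2(scoresFor(0, 120))$decision, "MCI")
  # 60/60 tie with higher summed AD score
  s <- scoresFor(60, 120)
  s[2, 1] <- 0.95; s[1, 1] <- 0.05
  expect_equal(voteStage2(s)$decision, "AD")
  # 60/60 tie with higher summed MCI score
  s2 <- scoresFor(60, 120)
  s2[1, 61] <- 0.99; s2[2, 61] <- 0.01
  expect_equal(voteStage2(s2)$decision, "MCI")
})

test_that("voting matches the direct rule on every tally with N <= 30", {
  for (n in 1:30) {
    for (k in 0:n) {
      s <- scoresFor(k, n)
      got1 <- voteStage1(s)
      expect_equal(got1$patientFraction, k / n)
      expect_equal(got1$decision,
                   c(first = "HC", second = "PATIENT")[[oracleVote(k, n)]])
      got2 <- voteStage2(s)
      # equal margins: the tie falls to MCI under the summed-score rule
      want2 <- if (k / n > 0.5) "AD" else "MCI"
      expect_equal(got2$decision, want2)
    }
  }
})

test_that("voting is invariant to item order and monotone in flips", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:25, 1)
    s <- matrix(runif(2 * n), 2, n)
    s <- sweep(s, 2, colSums(s), "/")
    perm <- sample(n)
    expect_equal(voteStage1(s)$decision, voteStage1(s[, perm,
                                                      drop = FALSE])$decision)
    # flipping one HC clip to PATIENT never flips the decision to HC
    v0 <- voteStage1(s)
    hcIdx <- which(apply(s, 2, which.max) == 1L)
    if (length(hcIdx) > 0 && v0$decision == "PATIENT") {
      s2 <- s
      s2[, hcIdx[1]] <- rev(s2[, hcIdx[1]])
      expect_equal(voteStage1(s2)$decision, "PATIENT")
    }
  }
})

test_that("the cascade consults EEG only after a patient decision", {
  params <- gaitSimParams(framesPerRecord = 66L)
  eparams <- eegSimParams(samplingRate = 250, duration = 6)
  hc <- methods::new("SubjectRecord", subjectId = "h1", label = "HC",
                     gait = generateGaitRecord(params, "HC", "h1", 1),
                     eegOpen = NULL, eegClosed = NULL)
  ad <- methods::new("SubjectRecord", subjectId = "a1", label = "AD",
                     gait = generateGaitRecord(params, "AD", "a1", 2),
                     eegOpen = generateEEGRecord(eparams, "AD",
                                                 "eyes_open", "a1", 2),
                     eegClosed = generateEEGRecord(eparams, "AD",
                                                   "eyes_closed", "a1", 2))
  noEeg <- methods::new("SubjectRecord", subjectId = "a2", label = "MCI",
                        gait = generateGaitRecord(params, "AD", "a2", 3),
                        eegOpen = NULL, eegClosed = NULL)
  gaitPrep <- list(theta = -27, window = 60L, stride = 3L,
                   jointSubset = defaultJointSubset(), rootIndex = 1L)
  eegPrep <- list(targetRate = 250, window = 256L, epochsPerSubject = 4L)
  s1 <- astGcnModel(tinyGaitConfig(), seed = 1)
  s2 <- stCnnModel(seed = 1)
  # force stage 1 to always say HC: bias the head hard toward class 1
  s1hc <- s1
  s1hc@layers[[length(s1hc@layers)]]$params$W[] <- 0
  s1hc@layers[[length(s1hc@layers)]]$params$b <- c(10, -10)
  mHc <- cascadeModel(s1hc, s2, gaitPrep, eegPrep)
  pr <- classifySubject(mHc, hc)
  expect_equal(pr@label, "HC")
  expect_true(is.na(pr@stage2Fraction))      # stage-2 fields absent
  # force stage 1 to always say PATIENT
  s1p <- s1
  s1p@layers[[length(s1p@layers)]]$params$W[] <- 0
  s1p@layers[[length(s1p@layers)]]$params$b <- c(-10, 10)
  mP <- cascadeModel(s1p, s2, gaitPrep, eegPrep)
  pa <- classifySubject(mP, ad)
  expect_true(pa@label %in% c("MCI", "AD"))
  expect_false(is.na(pa@stage2Fraction))
  # patient decision without EEG is an explicit needs-eeg outcome
  pn <- classifySubject(mP, noEeg)
  expect_equal(pn@status, "needs-eeg")
  expect_true(is.na(pn@label))
})

test_that("evaluation metrics follow their defining identities", {
  df <- data.frame(
    subject_id = sprintf("s%d", 1:9),
    truth = rep(c("HC", "MCI", "AD"), each = 3),
    stage1_fraction = 0.5, stage2_fraction = NA,
    predicted = rep("HC", 9), status = "ok")
  m <- adcascade:::cascadeMetrics(df)
  expect_equal(m$threeWayAccuracy, 1 / 3)    # all-HC on a balanced set
  expect_equal(m$stage1Accuracy, 1 / 3)
  # three-way accuracy equals the trace of the normalized confusion matrix
  expect_equal(m$threeWayAccuracy,
               sum(diag(m$confusion[, 1:3])) / sum(m$confusion))
  # perfect predictions give accuracy one everywhere
  df2 <- df
  df2$predicted <- df2$truth
  m2 <- adcascade:::cascadeMetrics(df2)
  expect_equal(m2$stage1Accuracy, 1)
  expect_equal(m2$stage2Accuracy, 1)
  expect_equal(m2$threeWayAccuracy, 1)
})

test_that("training is seed-reproducible and rejects foreign labels", {
  set.seed(43)
  plan <- data.frame(inCh = c(3L, 4L), outCh = c(4L, 8L), ks = c(1L, 6L),
                     kt = c(9L, 9L), stride = c(2L, 4L))
  m <- stCnnModel(stCnnConfig(C = 6, timeExtent = 64, plan = plan),
                  seed = 2)
  plane <- array(rnorm(6 * 64 * 12), c(6, 64, 12))
  ep <- methods::new("EEGEpochSet", data = plane,
                     subjectId = rep("s", 12),
                     label = rep(c("MCI", "AD"), 6), window = 32L,
                     channelLabels = sprintf("c%d", 1:6))
  cfg <- trainConfig("eeg", epochs = 2L, batchSize = 4L, seed = 9)
  f1 <- trainModel(m, ep, config = cfg)
  f2 <- trainModel(m, ep, config = cfg)
  expect_equal(nrow(f1$history), 2L)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_error(trainModel(m, ep, labels = replace(ep@label, 1, "HC"),
                          config = cfg),
               "outside the stage's class set")
})

test_that("loss decreases on a separable toy problem", {
  set.seed(44)
  plan <- data.frame(inCh = c(3L, 4L), outCh = c(4L, 8L), ks = c(1L, 4L),
                     kt = c(9L, 9L), stride = c(2L, 4L))
  m <- stCnnModel(stCnnConfig(C = 4, timeExtent = 64, plan = plan),
                  seed = 3)
  n <- 24
  plane <- array(rnorm(4 * 64 * n), c(4, 64, n))
  lab <- rep(c("MCI", "AD"), n / 2)
  # separable: AD epochs get a strong offset pattern
  plane[, , lab == "AD"] <- plane[, , lab == "AD"] + 2
  ep <- methods::new("EEGEpochSet", data = plane,
                     subjectId = rep("s", n), label = lab, window = 32L,
                     channelLabels = sprintf("c%d", 1:4))
  fit <- trainModel(m, ep, config = trainConfig("eeg", epochs = 10L,
                                                lr = 0.01,
                                                batchSize = 8L, seed = 1))
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_gt(tail(fit$history$accuracy, 1), 0.75)
})
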