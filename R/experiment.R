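#' @include cascade.R synthetic.R
NULL

#' Stratified subject-wise train/test split
#'
#' Randomly selects `fraction` of the subjects of each group for training
#' (round per group), the rest for testing. Disjoint and exhaustive;
#' reproducible for a fixed seed.
#'
#' @param cohort a [Cohort-class].
#' @param fraction training fraction (default 0.75).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitSubjects <- function(cohort, fraction = 0.75, seed = 1L) {
  labels <- cohort@manifest$label
  train <- withSeed(seed, {
    unlist(lapply(unique(labels), function(g) {
      idx <- which(labels == g)
      sample(idx, round(fraction * length(idx)))
    }))
  })
  list(train = sort(train),
       test = sort(setdiff(seq_along(labels), train)))
}

#' Run the full cascade experiment on a cohort
#'
#' Preprocesses gait and EEG, trains both stage models, and evaluates: clip-
#' and epoch-level accuracies on the respective test splits and subject-level
#' cascade metrics on the held-out (gait-split) test subjects. The gait split
#' is subject-wise; the EEG split is epoch-wise by default
#' (`eegSplitBy = "subject"` switches to the leakage-free protocol).
#'
#' @param cohort a [Cohort-class] (e.g. from [generateCohort()]).
#' @param gaitConfig an [astGcnConfig()] for the stage-1 model.
#' @param gaitTrain,eegTrain [trainConfig()] objects.
#' @param gaitPrep,eegPrep preprocessing parameter lists (see
#'   [cascadeModel()]).
#' @param subjectFraction train fraction for the subject-wise gait split.
#' @param eegSplitBy `"epoch"` or `"subject"`.
#' @param seed master seed (threads model init and both splits).
#' @return list with `model` ([CascadeModel-class]), `metrics`
#'   (subject-level, see [evaluateCascade()]), `clipAccuracy`,
#'   `epochAccuracy`, `histories`, and the index `split`.
#' @export
runCascadeExperiment <- function(cohort,
                                 gaitConfig = astGcnConfig(),
                                 gaitTrain = trainConfig("gait"),
                                 eegTrain = trainConfig("eeg"),
                                 gaitPrep = list(theta = -27, window = 60L,
                                                 stride = 3L,
                                                 jointSubset =
                                                   defaultJointSubset(),
                                                 rootIndex = 1L),
                                 eegPrep = list(targetRate = 250,
                                                window = 256L,
                                                epochsPerSubject = 120L),
                                 subjectFraction = 0.75,
                                 eegSplitBy = "epoch",
                                 seed = 1L) {
  subjects <- cohort@subjects
  labels <- cohort@manifest$label
  split <- splitSubjects(cohort, subjectFraction, seed = seed)

  stage1Label <- ifelse(labels == "HC", "HC", "PATIENT")
  clipSetFor <- function(idx) {
    bindClipSets(lapply(idx, function(i)
      prepGaitClips(subjects[[i]], gaitPrep, label = stage1Label[i])))
  }
  trainClips <- clipSetFor(split$train)
  testClips <- clipSetFor(split$test)

  gaitModel <- astGcnModel(gaitConfig, seed = seed)
  gaitFit <- trainModel(gaitModel, trainClips, config = gaitTrain)
  clipAcc <- scoreAccuracy(astGcnForward(gaitFit$model, testClips),
                           testClips@label, STAGE1_CLASSES)

  hasEeg <- vapply(subjects, function(s)
    !is.null(s@eegOpen) && !is.null(s@eegClosed), logical(1))
  eegIdx <- which(labels %in% c("MCI", "AD") & cohort@manifest$has_eeg &
                    hasEeg)
  stage2Fit <- NULL
  epochAcc <- NA_real_
  eegHistory <- NULL
  stage2Model <- NULL
  if (length(eegIdx) > 0) {
    allEpochs <- bindEpochSets(lapply(eegIdx, function(i)
      prepEegEpochs(subjects[[i]], eegPrep, label = labels[i])))
    eegSplit <- splitEpochs(allEpochs, 0.75, seed = seed, by = eegSplitBy)
    rm(allEpochs)
    eegModel <- stCnnModel(stCnnConfig(
      C = length(eegSplit$train@channelLabels),
      timeExtent = 2L * eegSplit$train@window), seed = seed)
    stage2Fit <- trainModel(eegModel, eegSplit$train, config = eegTrain)
    epochAcc <- scoreAccuracy(stCnnForward(stage2Fit$model, eegSplit$test),
                              eegSplit$test@label, STAGE2_CLASSES)
    eegHistory <- stage2Fit$history
    stage2Model <- stage2Fit$model
  }

  model <- cascadeModel(gaitFit$model, stage2Model,
                        gaitPrep = gaitPrep, eegPrep = eegPrep)
  metrics <- evaluateCascade(model, subjects[split$test])
  list(model = model, metrics = metrics,
       clipAccuracy = clipAcc, epochAccuracy = epochAcc,
       histories = list(gait = gaitFit$history, eeg = eegHistory),
       split = split)
}

#' Simulate an EEG epoch cohort (memory-lean)
#'
#' Generates MCI/AD subjects one at a time, runs the EEG preprocessing
#' chain (common-average re-referencing, downsampling, paired epoching) and
#' keeps only the epochs, so large cohorts (e.g. 52 subjects x 120 epochs)
#' never hold all raw recordings at once.
#'
#' @param nMci,nAd subjects per group.
#' @param epochsPerSubject epochs emitted per subject.
#' @param params an [eegSimParams()] list; its duration must cover
#'   `epochsPerSubject` windows after downsampling.
#' @param targetRate downsampling target in Hz.
#' @param window per-condition epoch window in samples.
#' @param seed master seed.
#' @return an [EEGEpochSet-class].
#' @export
simulateEpochCohort <- function(nMci = 26L, nAd = 26L,
                                epochsPerSubject = 120L,
                                params = eegSimParams(samplingRate = 250,
                                                      duration = 125),
                                targetRate = 250, window = 256L,
                                seed = 1L) {
  groups <- c(rep("MCI", nMci), rep("AD", nAd))
  total <- length(groups) * epochsPerSubject
  data <- NULL                      # preallocated on the first subject
  subjectIds <- character(total)
  labels <- character(total)
  chLabels <- NULL
  for (k in seq_along(groups)) {
    id <- sprintf("%s%03d", groups[k], k)
    sseed <- (seed + 104729L * k) %% 2147483647L
    prep <- function(cond) {
      rec <- generateEEGRecord(params, groups[k], cond, id, seed = sseed)
      downsampleRecord(rereferenceCommonAverage(rec), targetRate)
    }
    ep <- extractEpochs(prep("eyes_open"), prep("eyes_closed"),
                        window = window,
                        epochsPerSubject = epochsPerSubject,
                        label = groups[k])
    if (is.null(data)) {
      data <- array(0, c(dim(ep@data)[1:2], total))
      chLabels <- ep@channelLabels
    }
    at <- (k - 1L) * epochsPerSubject
    data[, , at + seq_len(epochsPerSubject)] <- ep@data
    subjectIds[at + seq_len(epochsPerSubject)] <- ep@subjectId
    labels[at + seq_len(epochsPerSubject)] <- ep@label
  }
  methods::new("EEGEpochSet", data = data, subjectId = subjectIds,
               label = labels, window = as.integer(window),
               channelLabels = chLabels)
}
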