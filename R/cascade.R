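#' @include astgcn.R stcnn.R
NULL

#' Stage-1 majority vote over gait clips
#'
#' A subject is voted `PATIENT` iff strictly more than 50% of the clips have
#' the patient class as their argmax score; otherwise `HC`. The fraction is
#' reported exactly. Voting is invariant to clip order.
#'
#' @param clipScores numeric `2 x N` score matrix (rows HC, PATIENT), e.g.
#'   from [astGcnForward()].
#' @return list with `patientFraction` and `decision` (`"HC"` or
#'   `"PATIENT"`).
#' @export
#' @examples
#' voteStage1(matrix(c(0.4, 0.6, 0.7, 0.3), 2))  # 1 of 2 patient -> HC
voteStage1 <- function(clipScores) {
  clipScores <- as.matrix(clipScores)
  if (ncol(clipScores) == 0L) stop("stage-1 vote requires at least one clip")
  stopifnot(nrow(clipScores) == 2L)
  votes <- apply(clipScores, 2L, which.max) == 2L
  frac <- mean(votes)
  list(patientFraction = frac,
       decision = if (frac > 0.5) "PATIENT" else "HC")
}

#' Stage-2 majority vote over EEG epochs
#'
#' The majority argmax class over epochs wins (AD iff strictly more than
#' half the epochs are voted AD, MCI iff strictly more than half are voted
#' MCI). An exact tie - possible only for even epoch counts - is broken by
#' the higher summed class score; should those also tie exactly, MCI is
#' returned (deterministic, no severity escalation without evidence).
#'
#' @param epochScores numeric `2 x N` score matrix (rows MCI, AD), e.g.
#'   from [stCnnForward()].
#' @return list with `adFraction` and `decision` (`"MCI"` or `"AD"`).
#' @export
voteStage2 <- function(epochScores) {
  epochScores <- as.matrix(epochScores)
  if (ncol(epochScores) == 0L)
    stop("stage-2 vote requires at least one epoch")
  stopifnot(nrow(epochScores) == 2L)
  votes <- apply(epochScores, 2L, which.max) == 2L
  frac <- mean(votes)
  decision <- if (frac > 0.5) "AD"
    else if (frac < 0.5) "MCI"
    else if (sum(epochScores[2L, ]) > sum(epochScores[1L, ])) "AD"
    else "MCI"
  list(adFraction = frac, decision = decision)
}

#' Assemble a cascade model
#'
#' @param stage1 a trained [AstGcnModel-class].
#' @param stage2 a trained [StCnnModel-class] (or `NULL`).
#' @param gaitPrep list: `theta` (rotation, degrees), `window`, `stride`,
#'   `jointSubset` (or `NULL`), `rootIndex`.
#' @param eegPrep list: `targetRate`, `window`, `epochsPerSubject`.
#' @return a [CascadeModel-class].
#' @export
cascadeModel <- function(stage1, stage2 = NULL,
                         gaitPrep = list(theta = -27, window = 60L,
                                         stride = 3L,
                                         jointSubset = defaultJointSubset(),
                                         rootIndex = 1L),
                         eegPrep = list(targetRate = 250, window = 256L,
                                        epochsPerSubject = 120L)) {
  methods::new("CascadeModel", stage1 = stage1, stage2 = stage2,
               gaitPrep = gaitPrep, eegPrep = eegPrep)
}

# Rotation, centering, windowing and key-point selection for one subject.
prepGaitClips <- function(subject, gaitPrep, label = NA) {
  rec <- subject@gait
  if (is.null(rec)) stop("subject '", subject@subjectId, "' has no gait data")
  if (rec@view != "front")
    stop("subject '", subject@subjectId,
         "': only front-view records enter the gait pipeline")
  rec <- rotateRecord(rec, gaitPrep$theta)
  rec <- centerRecord(rec, gaitPrep$rootIndex %||% 1L)
  clips <- extractClips(rec, gaitPrep$window %||% 60L,
                        gaitPrep$stride %||% 3L, label = label)
  if (!is.null(gaitPrep$jointSubset))
    clips <- selectJoints(clips, gaitPrep$jointSubset)
  clips
}

# Re-referencing, downsampling and paired epoching for one subject.
prepEegEpochs <- function(subject, eegPrep, label = NA) {
  if (is.null(subject@eegOpen) || is.null(subject@eegClosed))
    stop("subject '", subject@subjectId, "' lacks EEG data")
  prep <- function(rec) {
    if (all(c("Ref", "Gnd") %in% rec@channelLabels))
      rec <- rereferenceCommonAverage(rec)
    downsampleRecord(rec, eegPrep$targetRate %||% 250)
  }
  extractEpochs(prep(subject@eegOpen), prep(subject@eegClosed),
                window = eegPrep$window %||% 256L,
                epochsPerSubject = eegPrep$epochsPerSubject %||% 120L,
                label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one subject through the cascade
#'
#' Stage 1 votes over all gait clips; the EEG is consulted only when the
#' stage-1 decision is `PATIENT`, in which case stage 2 votes over all the
#' subject's epochs. A patient decision for a subject without EEG data
#' yields an explicit `needs-eeg` outcome (label `NA`), never a silent HC.
#'
#' @param model a [CascadeModel-class].
#' @param subject a [SubjectRecord-class] with gait data.
#' @return a [CascadePrediction-class].
#' @export
classifySubject <- function(model, subject) {
  clips <- prepGaitClips(subject, model@gaitPrep)
  if (nClips(clips) == 0L)
    stop("subject '", subject@subjectId, "' yields no gait clips")
  v1 <- voteStage1(astGcnForward(model@stage1, clips))
  if (v1$decision == "HC") {
    return(methods::new("CascadePrediction", subjectId = subject@subjectId,
                        stage1Fraction = v1$patientFraction,
                        stage2Fraction = NA_real_, label = "HC",
                        status = "ok"))
  }
  if (is.null(subject@eegOpen) || is.null(subject@eegClosed) ||
      is.null(model@stage2)) {
    return(methods::new("CascadePrediction", subjectId = subject@subjectId,
                        stage1Fraction = v1$patientFraction,
                        stage2Fraction = NA_real_, label = NA_character_,
                        status = "needs-eeg"))
  }
  epochs <- prepEegEpochs(subject, model@eegPrep)
  v2 <- voteStage2(stCnnForward(model@stage2, epochs))
  methods::new("CascadePrediction", subjectId = subject@subjectId,
               stage1Fraction = v1$patientFraction,
               stage2Fraction = v2$adFraction, label = v2$decision,
               status = "ok")
}

#' Training configuration
#'
#' Defaults follow the stage-specific settings: stochastic gradient descent
#' with batch size 64; gait stage with initial learning rate 0.05 for 50
#' epochs; EEG stage with 0.005 for 70 epochs. The learning rate is held
#' constant (no decay schedule).
#'
#' @param stage `"gait"` or `"eeg"`.
#' @param lr learning rate (stage default when `NULL`).
#' @param epochs training epochs (stage default when `NULL`).
#' @param batchSize minibatch size.
#' @param seed seed for shuffling and dropout.
#' @return list of class `"trainConfig"`.
#' @export
trainConfig <- function(stage = c("gait", "eeg"), lr = NULL, epochs = NULL,
                        batchSize = 64L, seed = 1L) {
  stage <- match.arg(stage)
  lr <- lr %||% switch(stage, gait = 0.05, eeg = 0.005)
  epochs <- epochs %||% switch(stage, gait = 50L, eeg = 70L)
  structure(list(stage = stage, lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = seed,
                 optimizer = "sgd"),
            class = "trainConfig")
}

# Core SGD loop over a batch accessor. Returns updated layers + history.
trainLayers <- function(layers, getBatch, y, cfg) {
  n <- length(y)
  if (n == 0L) stop("empty training set")
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  withSeed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      correct <- 0L
      for (start in seq(1L, n, by = cfg$batchSize)) {
        idx <- perm[start:min(start + cfg$batchSize - 1L, n)]
        x <- getBatch(idx)
        f <- nnModelForward(layers, x, training = TRUE)
        layers <- f$layers
        ce <- softmaxCrossEntropy(f$y, y[idx])
        losses <- c(losses, ce$loss)
        correct <- correct + sum(apply(ce$probs, 2L, which.max) == y[idx])
        b <- nnModelBackward(layers, f$caches, ce$dlogits)
        layers <- nnSgdStep(layers, b$grads, cfg$lr)
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses),
                                  accuracy = correct / n))
    }
  })
  list(layers = layers, history = history)
}

#' Train a stage model
#'
#' Minimizes softmax cross-entropy with stochastic gradient descent at a
#' constant learning rate. Reproducible for a fixed seed on a single
#' worker. The history records per-epoch mean batch loss and training
#' accuracy.
#'
#' @param model an [AstGcnModel-class] or [StCnnModel-class].
#' @param data a [GaitClipSet-class] / [EEGEpochSet-class] (labels may be
#'   carried by the set) or a raw input array.
#' @param labels character labels in the model's class set; defaults to the
#'   labels carried by `data`.
#' @param config a [trainConfig()].
#' @return list with `model` (trained) and `history` (data.frame).
#' @export
trainModel <- function(model, data, labels = NULL, config = NULL) {
  if (is(model, "AstGcnModel")) {
    config <- config %||% trainConfig("gait")
    x <- if (is(data, "GaitClipSet")) data@data else data
    labels <- labels %||% if (is(data, "GaitClipSet")) data@label else NULL
    getBatch <- function(idx) sliceLast(x, idx)
    n <- dim(x)[4L]
  } else if (is(model, "StCnnModel")) {
    config <- config %||% trainConfig("eeg")
    if (is(data, "EEGEpochSet")) {
      labels <- labels %||% data@label
      plane <- data@data
      getBatch <- function(idx)
        replicateEpochPlanes(plane[, , idx, drop = FALSE])
      n <- dim(plane)[3L]
    } else {
      getBatch <- function(idx) sliceLast(data, idx)
      n <- dim(data)[4L]
    }
  } else stop("unsupported model class: ", class(model))
  if (is.null(labels)) stop("labels are required")
  if (length(labels) != n) stop("one label per training item required")
  bad <- setdiff(unique(labels), model@classes)
  if (length(bad))
    stop("label(s) outside the stage's class set: ",
         paste(bad, collapse = ", "))
  yIdx <- match(labels, model@classes)
  fit <- trainLayers(model@layers, getBatch, yIdx, config)
  model@layers <- fit$layers
  list(model = model, history = fit$history)
}

#' Subject-level cascade evaluation
#'
#' Applies the cascade to every subject and reports: stage-1 binary
#' accuracy (HC vs patient over all subjects), stage-2 MCI-vs-AD accuracy
#' (over true patients that reached stage 2), three-way accuracy (needs-EEG
#' outcomes count as errors), and a confusion matrix whose prediction
#' columns are HC/MCI/AD/needs-eeg. The three-way accuracy equals the trace
#' of the (row-complete) normalized confusion matrix.
#'
#' @param model a [CascadeModel-class].
#' @param subjects list of [SubjectRecord-class] (or a [Cohort-class]).
#' @return list with `predictions` (data.frame), `stage1Accuracy`,
#'   `stage2Accuracy`, `threeWayAccuracy`, `confusion`, `needsEeg`.
#' @export
evaluateCascade <- function(model, subjects) {
  if (is(subjects, "Cohort")) subjects <- subjects@subjects
  preds <- lapply(subjects, function(s) classifySubject(model, s))
  truth <- vapply(subjects, groupLabel, character(1))
  predLab <- vapply(preds, function(p)
    if (is.na(p@label)) "needs-eeg" else p@label, character(1))
  df <- data.frame(
    subject_id = vapply(preds, subjectId, character(1)),
    truth = truth,
    stage1_fraction = vapply(preds, function(p) p@stage1Fraction,
                             numeric(1)),
    stage2_fraction = vapply(preds, function(p) p@stage2Fraction,
                             numeric(1)),
    predicted = predLab,
    status = vapply(preds, function(p) p@status, character(1)))
  cascadeMetrics(df)
}

# Metrics from a predictions data.frame (truth/predicted/status columns).
cascadeMetrics <- function(df) {
  s1True <- ifelse(df$truth == "HC", "HC", "PATIENT")
  s1Pred <- ifelse(df$predicted == "HC", "HC", "PATIENT")
  stage1 <- mean(s1True == s1Pred)
  reached <- df$truth %in% c("MCI", "AD") &
    df$predicted %in% c("MCI", "AD")
  stage2 <- if (any(reached))
    mean(df$truth[reached] == df$predicted[reached]) else NA_real_
  threeWay <- mean(df$truth == df$predicted)
  confusion <- table(
    truth = factor(df$truth, levels = GROUP_LEVELS),
    predicted = factor(df$predicted,
                       levels = c(GROUP_LEVELS, "needs-eeg")))
  list(predictions = df, stage1Accuracy = stage1, stage2Accuracy = stage2,
       threeWayAccuracy = threeWay, confusion = confusion,
       needsEeg = sum(df$status == "needs-eeg"))
}

#' Accuracy of per-item scores against labels
#'
#' @param scores `K x N` score matrix (class order = `classes`).
#' @param labels character vector of true labels.
#' @param classes class order of the score rows.
#' @return fraction of items whose argmax class matches the label.
#' @export
scoreAccuracy <- function(scores, labels, classes) {
  pred <- classes[apply(scores, 2L, which.max)]
  mean(pred == labels)
}
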