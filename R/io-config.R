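#' @include experiment.R io-skeleton.R io-edf.R
NULL

#' Default run configuration
#'
#' The full configuration driving [runPipeline()], serializable to a single
#' YAML file. Unknown keys in a user file are rejected.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    paths = list(dataRoot = NULL, outDir = "adcascade-run"),
    simulate = list(
      enabled = TRUE,
      subjectsPerGroup = list(HC = 10L, MCI = 10L, AD = 5L),
      gaitEffectSize = 1, eegEffectSize = 1,
      framesPerRecord = 90L, frameRate = 30,
      eegSamplingRate = 500, eegDuration = 30),
    gait = list(theta = -27, window = 60L, stride = 3L,
                useKeypointSubset = TRUE, rootIndex = 1L),
    eeg = list(targetRate = 250, window = 256L, epochsPerSubject = 24L,
               splitBy = "epoch"),
    model = list(
      gait = list(channels = c(16L, 16L, 32L, 32L),
                  strides = c(1L, 1L, 2L, 1L),
                  tKernel = 9L, attention = "after-3", dropout = 0.1)),
    train = list(
      gait = list(lr = 0.05, epochs = 10L, batchSize = 64L),
      eeg = list(lr = 0.005, epochs = 15L, batchSize = 64L))
  )
}

checkKeys <- function(cfg, ref, path = "") {
  if (!is.list(cfg) || !is.list(ref)) return(invisible(NULL))
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in intersect(names(cfg), names(ref))) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      checkKeys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  invisible(NULL)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a run configuration (YAML)
#'
#' `readRunConfig` merges the file over [defaultRunConfig()] after
#' rejecting unknown keys.
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return `readRunConfig` returns the merged configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- defaultRunConfig()
  checkKeys(user, ref)
  mergeConfig(ref, user)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Load a cohort from disk
#'
#' Expects skeleton records (CSV/JSON-lines) plus `manifest.tsv` under
#' `root/gait/`, and EDF files `<subject>_eyes_open.edf` /
#' `<subject>_eyes_closed.edf` under `root/eeg/` for patient subjects.
#'
#' @param root data root directory.
#' @return a [Cohort-class].
#' @export
loadCohort <- function(root) {
  ds <- readSkeletonDataset(file.path(root, "gait"))
  if (is.null(ds$manifest)) stop("no manifest.tsv under ", root, "/gait")
  man <- ds$manifest
  byId <- stats::setNames(ds$records,
                          vapply(ds$records, subjectId, character(1)))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$subject_id[i]
    eo <- ec <- NULL
    if (isTRUE(man$has_eeg[i])) {
      fo <- file.path(root, "eeg", paste0(id, "_eyes_open.edf"))
      fc <- file.path(root, "eeg", paste0(id, "_eyes_closed.edf"))
      if (file.exists(fo)) eo <- readEDF(fo, "eyes_open")
      if (file.exists(fc)) ec <- readEDF(fc, "eyes_closed")
    }
    methods::new("SubjectRecord", subjectId = id, label = man$label[i],
                 gait = byId[[id]], eegOpen = eo, eegClosed = ec)
  })
  methods::new("Cohort", subjects = subjects, manifest = man)
}

#' Run the whole pipeline from a configuration
#'
#' Simulate (optional) -> preprocess -> train stage 1 -> train stage 2 ->
#' cascade evaluation; writes metrics, confusion matrix, per-epoch training
#' histories, subject predictions, model checkpoints and a line-delimited
#' JSON log under the output directory. Fully reproducible from the
#' configuration and seed; any stage failure aborts with the stage name
#' and cause.
#'
#' @param config a configuration list (see [defaultRunConfig()]) or the
#'   path to a YAML file.
#' @param outDir optional override of `config$paths$outDir`.
#' @return the experiment result of [runCascadeExperiment()], invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  checkKeys(config, defaultRunConfig())
  outDir <- outDir %||% config$paths$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "log.jsonl")
  cat(NULL, file = logPath)
  logEvent <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logPath, append = TRUE, sep = "")
  }
  runStage <- function(name, expr) {
    logEvent(name, status = "start")
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logEvent(name, status = "done")
    r
  }

  seed <- config$seed
  cohort <- runStage("data", {
    if (isTRUE(config$simulate$enabled)) {
      sim <- config$simulate
      generateCohort(
        gaitSimParams(effectSize = sim$gaitEffectSize,
                      frameRate = sim$frameRate,
                      framesPerRecord = sim$framesPerRecord),
        eegSimParams(effectSize = sim$eegEffectSize,
                     samplingRate = sim$eegSamplingRate,
                     duration = sim$eegDuration),
        sizes = unlist(sim$subjectsPerGroup), seed = seed)
    } else {
      if (is.null(config$paths$dataRoot))
        stop("paths$dataRoot is required when simulation is disabled")
      loadCohort(config$paths$dataRoot)
    }
  })
  writeManifest(cohort@manifest, file.path(outDir, "manifest.tsv"))

  gaitPrep <- list(theta = config$gait$theta, window = config$gait$window,
                   stride = config$gait$stride,
                   jointSubset = if (isTRUE(config$gait$useKeypointSubset))
                     defaultJointSubset() else NULL,
                   rootIndex = config$gait$rootIndex)
  eegPrep <- list(targetRate = config$eeg$targetRate,
                  window = config$eeg$window,
                  epochsPerSubject = config$eeg$epochsPerSubject)
  mg <- config$model$gait
  gaitConfig <- astGcnConfig(channels = mg$channels, strides = mg$strides,
                             tKernel = mg$tKernel,
                             attention = mg$attention,
                             dropout = mg$dropout,
                             jointSubset = gaitPrep$jointSubset)
  res <- runStage("train-evaluate", runCascadeExperiment(
    cohort, gaitConfig,
    gaitTrain = trainConfig("gait", lr = config$train$gait$lr,
                            epochs = config$train$gait$epochs,
                            batchSize = config$train$gait$batchSize,
                            seed = seed),
    eegTrain = trainConfig("eeg", lr = config$train$eeg$lr,
                           epochs = config$train$eeg$epochs,
                           batchSize = config$train$eeg$batchSize,
                           seed = seed),
    gaitPrep = gaitPrep, eegPrep = eegPrep,
    eegSplitBy = config$eeg$splitBy, seed = seed))

  runStage("artifacts", {
    m <- res$metrics
    metrics <- list(clip_accuracy = res$clipAccuracy,
                    epoch_accuracy = res$epochAccuracy,
                    stage1_subject_accuracy = m$stage1Accuracy,
                    stage2_subject_accuracy = m$stage2Accuracy,
                    three_way_accuracy = m$threeWayAccuracy,
                    needs_eeg = m$needsEeg)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame.matrix(m$confusion),
                     file.path(outDir, "confusion.csv"))
    utils::write.csv(res$histories$gait,
                     file.path(outDir, "history_gait.csv"),
                     row.names = FALSE)
    if (!is.null(res$histories$eeg))
      utils::write.csv(res$histories$eeg,
                       file.path(outDir, "history_eeg.csv"),
                       row.names = FALSE)
    utils::write.table(m$predictions,
                       file.path(outDir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    saveRDS(res$model, file.path(outDir, "cascade_model.rds"))
    writeRunConfig(config, file.path(outDir, "config.yaml"))
  })
  invisible(res)
}
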