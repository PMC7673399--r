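#' @include AllGenerics.R
NULL

GROUP_LEVELS <- c("HC", "MCI", "AD")
STAGE1_CLASSES <- c("HC", "PATIENT")
STAGE2_CLASSES <- c("MCI", "AD")

#' SkeletonRecord: a Kinect V2 skeleton sequence for one subject
#'
#' Coordinates are stored as a `3 x V x T` array in meters (camera frame):
#' axis 1 is the coordinate component (x, y, z), axis 2 the joint, axis 3 the
#' frame. Only front-view records are admitted to the gait pipeline; the
#' back-view estimates of the sensor are less accurate.
#'
#' Joints follow the standard Kinect V2 25-joint layout; R index `k`
#' corresponds to SDK joint `k - 1` (see [kinectJointNames()]).
#'
#' @slot subjectId character scalar.
#' @slot coords numeric `3 x V x T` array, all values finite.
#' @slot frameIndex integer vector of length `T`.
#' @slot view `"front"` or `"back"`.
#' @slot jointScheme identifier of the joint layout (`"kinect-v2-25"`).
#' @export
setClass("SkeletonRecord",
  representation(subjectId = "character", coords = "array",
                 frameIndex = "integer", view = "character",
                 jointScheme = "character"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[1L] != 3L)
      return("coords must be a 3 x V x T array")
    if (d[3L] < 1L) return("record must contain at least one frame")
    if (!all(is.finite(object@coords)))
      return("coords contain non-finite values")
    if (length(object@frameIndex) != d[3L])
      return("frameIndex length must equal the number of frames")
    if (!object@view %in% c("front", "back"))
      return("view must be 'front' or 'back'")
    TRUE
  })

#' GaitClipSet: fixed-size gait clips cut from skeleton records
#'
#' Each clip is a `D x T x V` array (D = 3 coordinate components, T frames,
#' V joints); a set holds N clips as a `3 x T x V x N` array plus per-clip
#' subject ids and (optional) stage-1 labels.
#'
#' @slot data numeric `3 x T x V x N` array.
#' @slot subjectId character vector, one per clip.
#' @slot label character vector, one per clip; `"HC"`/`"PATIENT"` or `NA`.
#' @slot jointIndices integer vector: original (1-based) joint indices of the
#'   V retained joints, ascending.
#' @export
setClass("GaitClipSet",
  representation(data = "array", subjectId = "character",
                 label = "character", jointIndices = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L || d[1L] != 3L)
      return("data must be a 3 x T x V x N array")
    if (length(object@subjectId) != d[4L])
      return("one subjectId per clip required")
    if (length(object@label) != d[4L])
      return("one label per clip required")
    if (length(object@jointIndices) != d[3L])
      return("jointIndices must have one entry per joint")
    ok <- is.na(object@label) | object@label %in% STAGE1_CLASSES
    if (!all(ok)) return("labels must be HC/PATIENT or NA")
    TRUE
  })

#' SkeletonGraph: the spatial skeleton graph
#'
#' Undirected graph over the V joints of a single frame; edges are the
#' natural bone connections ("spatial edges"). The center joint anchors the
#' centripetal/centrifugal ordering used by the spatial-configuration
#' partitioning.
#'
#' @slot V integer joint count.
#' @slot edges integer `2 x E` matrix of 1-based joint indices.
#' @slot centerIndex integer, 1-based index of the center joint.
#' @export
setClass("SkeletonGraph",
  representation(V = "integer", edges = "matrix", centerIndex = "integer"),
  validity = function(object) {
    e <- object@edges
    if (nrow(e) != 2L) return("edges must be a 2 x E matrix")
    if (ncol(e) > 0) {
      if (any(e < 1L) || any(e > object@V))
        return("edge endpoints out of range")
      if (any(e[1L, ] == e[2L, ])) return("self-edges are not allowed")
      key <- paste(pmin(e[1L, ], e[2L, ]), pmax(e[1L, ], e[2L, ]))
      if (anyDuplicated(key)) return("duplicate edges")
    }
    if (object@centerIndex < 1L || object@centerIndex > object@V)
      return("centerIndex out of range")
    TRUE
  })

#' PartitionedAdjacency: spatial-configuration partition of A + I
#'
#' The neighbourhood of each node (including the node itself through the
#' self-connection matrix I) is split into three subsets: the root node
#' itself, the centripetal group (graph-closer to the body center than the
#' root) and the centrifugal group (farther). `masks` holds the three binary
#' masks, which are elementwise disjoint and sum exactly to A + I;
#' `normalized` holds the three degree-normalized operators
#' Lambda^{-1/2} B_k Lambda^{-1/2} with Lambda taken once from the full
#' A + I.
#'
#' @slot masks numeric `V x V x 3` binary array (root, centripetal,
#'   centrifugal).
#' @slot normalized list of three `V x V` matrices.
#' @slot degrees numeric vector: row degrees of A + I.
#' @slot centerIndex integer.
#' @export
setClass("PartitionedAdjacency",
  representation(masks = "array", normalized = "list", degrees = "numeric",
                 centerIndex = "integer"),
  validity = function(object) {
    d <- dim(object@masks)
    if (length(d) != 3L || d[3L] != 3L || d[1L] != d[2L])
      return("masks must be a V x V x 3 array")
    if (length(object@normalized) != 3L)
      return("three normalized subset matrices required")
    if (!all(object@masks %in% c(0, 1)))
      return("masks must be binary")
    tot <- object@masks[, , 1L] + object@masks[, , 2L] + object@masks[, , 3L]
    if (any(tot > 1)) return("subset masks must be disjoint")
    if (!all(vapply(object@normalized,
                    function(m) all(is.finite(m)), logical(1))))
      return("normalized entries must be finite")
    TRUE
  })

#' EEGRecord: one multichannel resting-state EEG recording
#'
#' @slot subjectId character scalar.
#' @slot condition `"eyes_open"` or `"eyes_closed"`.
#' @slot channelLabels character vector, one per data row (64 labels
#'   including `"Ref"` and `"Gnd"` before re-referencing).
#' @slot samplingRate numeric, Hz.
#' @slot data numeric channels x samples matrix, microvolts.
#' @export
setClass("EEGRecord",
  representation(subjectId = "character", condition = "character",
                 channelLabels = "character", samplingRate = "numeric",
                 data = "matrix"),
  validity = function(object) {
    if (!object@condition %in% c("eyes_open", "eyes_closed"))
      return("condition must be 'eyes_open' or 'eyes_closed'")
    if (length(object@channelLabels) != nrow(object@data))
      return("one channel label per data row required")
    if (object@samplingRate <= 0) return("samplingRate must be positive")
    TRUE
  })

#' EEGEpochSet: fixed-size EEG epochs for the stage-2 classifier
#'
#' Each epoch is conceptually a `3 x C x 2T` array: the i-th non-overlapping
#' window of the eyes-open record concatenated in time with the i-th window
#' of the eyes-closed record, replicated over three identical depth planes.
#' Because the planes are exact copies, the set stores a single plane
#' (`C x 2T x N`); [epochTensor()] materializes the replicated 3-plane
#' epoch bit-identically.
#'
#' @slot data numeric `C x 2T x N` array (single depth plane).
#' @slot subjectId character vector, one per epoch.
#' @slot label character vector, `"MCI"`/`"AD"` or `NA`.
#' @slot window integer: the per-condition window length T (so time extent
#'   is `2 * window`).
#' @slot channelLabels character vector of the C retained channels.
#' @export
setClass("EEGEpochSet",
  representation(data = "array", subjectId = "character", label = "character",
                 window = "integer", channelLabels = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a C x 2T x N array")
    if (d[2L] != 2L * object@window)
      return("time extent must equal 2 * window")
    if (length(object@subjectId) != d[3L])
      return("one subjectId per epoch required")
    if (length(object@label) != d[3L]) return("one label per epoch required")
    ok <- is.na(object@label) | object@label %in% STAGE2_CLASSES
    if (!all(ok)) return("labels must be MCI/AD or NA")
    if (length(object@channelLabels) != d[1L])
      return("one channel label per channel required")
    TRUE
  })

#' SubjectRecord: all raw data of one subject
#'
#' Healthy controls carry gait data only; patients carry gait plus both
#' EEG conditions (EEG is only consulted when stage 1 flags the subject as a
#' patient, mirroring the study design in which EEG was not collected from
#' controls).
#'
#' @slot subjectId character scalar.
#' @slot label `"HC"`, `"MCI"` or `"AD"` (or `NA` for unlabelled data).
#' @slot gait a [SkeletonRecord-class] or `NULL`.
#' @slot eegOpen an [EEGRecord-class] or `NULL`.
#' @slot eegClosed an [EEGRecord-class] or `NULL`.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", label = "character",
                 gait = "ANY", eegOpen = "ANY", eegClosed = "ANY"),
  validity = function(object) {
    if (!is.na(object@label) && !object@label %in% GROUP_LEVELS)
      return("label must be HC, MCI or AD")
    for (s in c("gait")) {
      if (!is.null(slot(object, s)) && !is(slot(object, s), "SkeletonRecord"))
        return("gait must be a SkeletonRecord or NULL")
    }
    for (s in c("eegOpen", "eegClosed")) {
      if (!is.null(slot(object, s)) && !is(slot(object, s), "EEGRecord"))
        return(paste(s, "must be an EEGRecord or NULL"))
    }
    TRUE
  })

#' Cohort: a set of subjects plus their label manifest
#'
#' @slot subjects list of [SubjectRecord-class] objects.
#' @slot manifest data.frame with columns `subject_id`, `label`, `has_eeg`.
#' @export
setClass("Cohort",
  representation(subjects = "list", manifest = "data.frame"),
  validity = function(object) {
    if (!all(vapply(object@subjects, is, logical(1), "SubjectRecord")))
      return("subjects must all be SubjectRecord objects")
    need <- c("subject_id", "label", "has_eeg")
    if (!all(need %in% names(object@manifest)))
      return("manifest must have subject_id, label, has_eeg columns")
    if (nrow(object@manifest) != length(object@subjects))
      return("manifest rows must match subject count")
    TRUE
  })

#' AstGcnModel: the stage-1 gait classifier
#'
#' Stacked spatial-temporal graph-convolution blocks over the (key-point)
#' skeleton graph with learnable edge-importance masks, optionally gated by
#' hourglass attention modules, ending in global average pooling and a
#' two-class softmax head (HC vs patient).
#'
#' @slot config list produced by [astGcnConfig()].
#' @slot layers internal layer stack.
#' @slot graph the [SkeletonGraph-class] the model operates on.
#' @slot partitions the [PartitionedAdjacency-class] operators.
#' @slot classes character, class order of the output scores.
#' @export
setClass("AstGcnModel",
  representation(config = "list", layers = "list", graph = "SkeletonGraph",
                 partitions = "PartitionedAdjacency", classes = "character"))

#' StCnnModel: the stage-2 EEG classifier
#'
#' Four modules of alternating spatial (across electrodes) and temporal
#' (across samples) convolutions, then flatten, a fully connected layer and
#' a two-class softmax head (MCI vs AD).
#'
#' @slot config list produced by [stCnnConfig()].
#' @slot layers internal layer stack.
#' @slot classes character, class order of the output scores.
#' @export
setClass("StCnnModel",
  representation(config = "list", layers = "list", classes = "character"))

#' CascadeModel: both trained stages plus the preprocessing settings
#'
#' @slot stage1 an [AstGcnModel-class].
#' @slot stage2 an [StCnnModel-class] (or `NULL` if stage 2 is unavailable).
#' @slot gaitPrep list: `theta`, `window`, `stride`, `jointSubset`,
#'   `rootIndex`.
#' @slot eegPrep list: `targetRate`, `window`, `epochsPerSubject`.
#' @export
setClass("CascadeModel",
  representation(stage1 = "AstGcnModel", stage2 = "ANY",
                 gaitPrep = "list", eegPrep = "list"))

#' CascadePrediction: the cascade's subject-level decision
#'
#' `stage2Fraction` and stage-2 outputs are absent (`NA`) when the final
#' label is `"HC"` (the EEG is never consulted then). A patient decision for
#' a subject without EEG data yields `status = "needs-eeg"` and an `NA`
#' label rather than a silent fallback.
#'
#' @slot subjectId character scalar.
#' @slot stage1Fraction numeric in `[0, 1]`: fraction of clips voted patient.
#' @slot stage2Fraction numeric in `[0, 1]` or `NA`: fraction of epochs
#'   voted AD.
#' @slot label `"HC"`, `"MCI"`, `"AD"`, or `NA` when EEG is required but
#'   missing.
#' @slot status `"ok"` or `"needs-eeg"`.
#' @export
setClass("CascadePrediction",
  representation(subjectId = "character", stage1Fraction = "numeric",
                 stage2Fraction = "numeric", label = "character",
                 status = "character"),
  validity = function(object) {
    if (object@stage1Fraction < 0 || object@stage1Fraction > 1)
      return("stage1Fraction must lie in [0, 1]")
    if (!is.na(object@stage2Fraction) &&
        (object@stage2Fraction < 0 || object@stage2Fraction > 1))
      return("stage2Fraction must lie in [0, 1]")
    if (identical(object@label, "HC") && !is.na(object@stage2Fraction))
      return("stage-2 fields must be absent for HC decisions")
    if (!is.na(object@label) && object@label %in% c("MCI", "AD") &&
        is.na(object@stage2Fraction))
      return("stage-2 fraction required for MCI/AD decisions")
    TRUE
  })

## ---- accessors ----

#' @describeIn SkeletonRecord subject identifier.
#' @param x object.
#' @export
setMethod("subjectId", "SkeletonRecord", function(x) x@subjectId)

#' @describeIn GaitClipSet per-clip subject identifiers.
#' @param x object.
#' @export
setMethod("subjectId", "GaitClipSet", function(x) x@subjectId)

#' @describeIn EEGRecord subject identifier.
#' @param x object.
#' @export
setMethod("subjectId", "EEGRecord", function(x) x@subjectId)

#' @describeIn EEGEpochSet per-epoch subject identifiers.
#' @param x object.
#' @export
setMethod("subjectId", "EEGEpochSet", function(x) x@subjectId)

#' @describeIn SubjectRecord subject identifier.
#' @param x object.
#' @export
setMethod("subjectId", "SubjectRecord", function(x) x@subjectId)

#' @describeIn CascadePrediction subject identifier.
#' @param x object.
#' @export
setMethod("subjectId", "CascadePrediction", function(x) x@subjectId)

#' @describeIn GaitClipSet per-clip stage-1 labels.
#' @export
setMethod("groupLabel", "GaitClipSet", function(x) x@label)

#' @describeIn EEGEpochSet per-epoch stage-2 labels.
#' @export
setMethod("groupLabel", "EEGEpochSet", function(x) x@label)

#' @describeIn SubjectRecord diagnostic group label.
#' @export
setMethod("groupLabel", "SubjectRecord", function(x) x@label)

#' @describeIn EEGRecord sampling rate in Hz.
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@samplingRate)

#' @describeIn EEGRecord channel labels.
#' @export
setMethod("channelLabels", "EEGRecord", function(x) x@channelLabels)

#' @describeIn EEGEpochSet labels of the retained channels.
#' @export
setMethod("channelLabels", "EEGEpochSet", function(x) x@channelLabels)

#' Number of frames in a skeleton record
#' @param record a [SkeletonRecord-class].
#' @return integer frame count.
#' @export
nFrames <- function(record) dim(record@coords)[3L]

#' Number of joints in a skeleton record
#' @param record a [SkeletonRecord-class].
#' @return integer joint count V.
#' @export
nJoints <- function(record) dim(record@coords)[2L]

#' Number of clips in a clip set
#' @param clips a [GaitClipSet-class].
#' @return integer clip count.
#' @export
nClips <- function(clips) dim(clips@data)[4L]

#' Number of epochs in an epoch set
#' @param epochs an [EEGEpochSet-class].
#' @return integer epoch count.
#' @export
nEpochs <- function(epochs) dim(epochs@data)[3L]

#' Clip data array
#'
#' @param clips a [GaitClipSet-class].
#' @param i optional clip index; if missing, the full `3 x T x V x N` array.
#' @return numeric array.
#' @export
clipArray <- function(clips, i) {
  if (missing(i)) clips@data
  else array(clips@data[, , , i], dim(clips@data)[1:3])
}

#' Materialize one 3-plane epoch tensor
#'
#' Replicates the stored single depth plane three times, producing the
#' `3 x C x 2T` epoch array consumed by the stage-2 classifier. Replication
#' at access time is bit-identical to storing three copies.
#'
#' @param epochs an [EEGEpochSet-class].
#' @param i epoch index.
#' @return numeric `3 x C x 2T` array.
#' @export
epochTensor <- function(epochs, i) {
  plane <- epochs@data[, , i]
  d <- dim(epochs@data)
  out <- array(0, c(3L, d[1L], d[2L]))
  for (p in 1:3) out[p, , ] <- plane
  out
}

## ---- show methods ----

setMethod("show", "SkeletonRecord", function(object) {
  d <- dim(object@coords)
  cat(sprintf("SkeletonRecord '%s': %d joints x %d frames (%s view, %s)\n",
              object@subjectId, d[2L], d[3L], object@view,
              object@jointScheme))
})

setMethod("show", "GaitClipSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("GaitClipSet: %d clips of %d x %d x %d (D x T x V), %d subjects\n",
              d[4L], d[1L], d[2L], d[3L],
              length(unique(object@subjectId))))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d joints, %d spatial edges, center joint %d\n",
              object@V, ncol(object@edges), object@centerIndex))
})

setMethod("show", "PartitionedAdjacency", function(object) {
  v <- dim(object@masks)[1L]
  cat(sprintf(
    "PartitionedAdjacency: %d nodes; root/centripetal/centrifugal entries %d/%d/%d\n",
    v, sum(object@masks[, , 1L]), sum(object@masks[, , 2L]),
    sum(object@masks[, , 3L])))
})

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf(
    "EEGRecord '%s' (%s): %d channels x %d samples @ %g Hz\n",
    object@subjectId, object@condition, nrow(object@data),
    ncol(object@data), object@samplingRate))
})

setMethod("show", "EEGEpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EEGEpochSet: %d epochs of 3 x %d x %d (depth-replicated), %d subjects\n",
    d[3L], d[1L], d[2L], length(unique(object@subjectId))))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s' [%s]: gait=%s, eeg=%s\n",
              object@subjectId, object@label,
              if (is.null(object@gait)) "no" else "yes",
              if (is.null(object@eegOpen)) "no" else "both conditions"))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(factor(object@manifest$label, levels = GROUP_LEVELS))
  cat(sprintf("Cohort: %d subjects (HC %d, MCI %d, AD %d), %d with EEG\n",
              length(object@subjects), tab[["HC"]], tab[["MCI"]],
              tab[["AD"]], sum(object@manifest$has_eeg)))
})

setMethod("show", "AstGcnModel", function(object) {
  cat(sprintf(
    "AstGcnModel: %d ST-GCN blocks (channels %s), attention '%s', %d joints, %d parameters\n",
    length(object@config$channels),
    paste(object@config$channels, collapse = ","),
    object@config$attention, object@graph@V, parameterCount(object)))
})

setMethod("show", "StCnnModel", function(object) {
  cat(sprintf(
    "StCnnModel: %d ST-CNN modules on 3 x %d x %d input, %d parameters\n",
    nrow(object@config$plan), object@config$C, object@config$timeExtent,
    parameterCount(object)))
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel (stage 1: gait AST-GCN; stage 2: EEG ST-CNN)\n")
  show(object@stage1)
  if (!is.null(object@stage2)) show(object@stage2)
})

setMethod("show", "CascadePrediction", function(object) {
  cat(sprintf(
    "CascadePrediction '%s': label=%s (patient fraction %.3f%s, status %s)\n",
    object@subjectId, ifelse(is.na(object@label), "<needs EEG>", object@label),
    object@stage1Fraction,
    if (is.na(object@stage2Fraction)) ""
    else sprintf(", AD fraction %.3f", object@stage2Fraction),
    object@status))
})
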