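#' @include AllClasses.R
NULL

#' Kinect V2 joint names in index order
#'
#' The standard 25-joint layout of the Kinect V2 SDK. R index `k` is SDK
#' joint `k - 1`: SpineBase is index 1 here (SDK 0).
#'
#' @return Named character vector of length 25 (names are the R indices).
#' @export
#' @examples
#' kinectJointNames()[1]  # SpineBase
kinectJointNames <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft",
    "HandTipRight", "ThumbRight")
}

#' Bone connections of the Kinect V2 skeleton
#'
#' The 24 natural bone connections (spatial edges) of the 25-joint layout,
#' as 1-based index pairs. They form a spanning tree of the skeleton.
#'
#' @return integer `2 x 24` matrix.
#' @export
kinectEdges <- function() {
  e <- rbind(
    c(1, 2), c(2, 21), c(21, 3), c(3, 4),          # spine and head
    c(21, 5), c(5, 6), c(6, 7), c(7, 8),           # left arm
    c(8, 22), c(8, 23),
    c(21, 9), c(9, 10), c(10, 11), c(11, 12),      # right arm
    c(12, 24), c(12, 25),
    c(1, 13), c(13, 14), c(14, 15), c(15, 16),     # left leg
    c(1, 17), c(17, 18), c(18, 19), c(19, 20))     # right leg
  t(matrix(as.integer(e), ncol = 2L))
}

#' Default key-point joint subset: lower body plus right upper limb
#'
#' The 15 joints retained by key-point filtering: SpineBase (kept as the
#' graph root), both legs (hip/knee/ankle/foot), and the right arm
#' (shoulder/elbow/wrist/hand/hand-tip/thumb). Gait speed, cadence and
#' stride live in the lower body; in right-handed patients the right upper
#' limb is controlled by the hemisphere more affected early in the disease.
#'
#' @return sorted integer vector of 1-based joint indices.
#' @export
defaultJointSubset <- function() {
  sort(as.integer(c(1, 13:20, 9:12, 24, 25)))
}

#' Bridging edges for the default key-point subgraph
#'
#' Removing intermediate joints disconnects bones; the affected chains are
#' re-linked so the key-point graph stays connected. With the default subset
#' the only break is the right shoulder's path over SpineShoulder/SpineMid,
#' bridged by connecting ShoulderRight directly to SpineBase.
#'
#' @return integer `2 x B` matrix of 1-based index pairs (original indexing).
#' @export
defaultJointBridges <- function() {
  matrix(c(1L, 9L), nrow = 2L)
}

#' Construct a SkeletonRecord
#'
#' @param subjectId character scalar.
#' @param coords numeric `3 x V x T` array of camera-frame coordinates in
#'   meters.
#' @param view `"front"` (default) or `"back"`.
#' @param frameIndex optional integer frame indices (defaults to
#'   `0:(T-1)`).
#' @param jointScheme joint layout identifier.
#' @return a [SkeletonRecord-class].
#' @export
skeletonRecord <- function(subjectId, coords, view = "front",
                           frameIndex = NULL, jointScheme = "kinect-v2-25") {
  if (!all(is.finite(coords)))
    stop("record '", subjectId, "' rejected: non-finite joint coordinates")
  t <- dim(coords)[3L]
  if (is.null(frameIndex)) frameIndex <- seq_len(t) - 1L
  methods::new("SkeletonRecord", subjectId = as.character(subjectId),
               coords = coords, frameIndex = as.integer(frameIndex),
               view = view, jointScheme = jointScheme)
}

rotationMatrixX <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), sin(th),
           0, -sin(th), cos(th)), 3L, 3L)
}

#' Rotate all joint coordinates around the x-axis
#'
#' Applies the rotation `R_x(theta)` to every joint in every frame. The
#' acquisition cameras are ceiling-mounted at a 27 degree tilt; rotating by
#' -27 degrees brings the skeletons into a horizontal position relative to
#' the camera.
#'
#' @param record a [SkeletonRecord-class].
#' @param theta rotation angle in degrees (default -27).
#' @return the rotated [SkeletonRecord-class]; frame count and joint count
#'   are unchanged.
#' @export
#' @examples
#' rec <- skeletonRecord("s1", array(rnorm(3 * 25 * 5), c(3, 25, 5)))
#' rot <- rotateRecord(rec, -27)
rotateRecord <- function(record, theta = -27) {
  stopifnot(is.finite(theta))
  if (!all(is.finite(record@coords)))
    stop("record '", record@subjectId,
         "' rejected: non-finite joint coordinates")
  r <- rotationMatrixX(theta)
  d <- dim(record@coords)
  m <- r %*% matrix(record@coords, 3L)
  dim(m) <- d
  methods::initialize(record, coords = m)
}

#' Re-center every frame on a root joint
#'
#' Moves the coordinate origin to the chosen root joint (by default
#' SpineBase, joint index 1): in every frame tau each joint p becomes
#' `v_tau_p - v_tau_root`, so the root is exactly (0,0,0) in every frame.
#' The operation is idempotent.
#'
#' @param record a [SkeletonRecord-class].
#' @param rootIndex 1-based joint index of the root (default 1, SpineBase).
#' @return the centered [SkeletonRecord-class].
#' @export
centerRecord <- function(record, rootIndex = 1L) {
  v <- nJoints(record)
  if (rootIndex < 1L || rootIndex > v)
    stop("rootIndex ", rootIndex, " out of range for ", v, " joints")
  x <- record@coords
  root <- x[, rootIndex, , drop = FALSE]       # 3 x 1 x T
  x <- x - root[, rep(1L, v), , drop = FALSE]
  methods::initialize(record, coords = x)
}

#' Cut fixed-size gait clips from a record with a sliding window
#'
#' Windows start at frames 1, 1 + stride, 1 + 2*stride, ...; a record of
#' length L yields `floor((L - window)/stride) + 1` clips (0 when
#' L < window). Records shorter than the window are not padded - padding
#' would fabricate gait frames - they yield an empty set with a warning.
#'
#' @param record a [SkeletonRecord-class] (front view).
#' @param window clip length in frames (default 60).
#' @param stride window stride in frames (default 3).
#' @param label optional stage-1 label (`"HC"` or `"PATIENT"`) attached to
#'   every clip.
#' @return a [GaitClipSet-class] with clips shaped `3 x window x V`.
#' @export
extractClips <- function(record, window = 60L, stride = 3L, label = NA) {
  stopifnot(window >= 1L, stride >= 1L)
  l <- nFrames(record)
  v <- nJoints(record)
  n <- if (l >= window) (l - window) %/% stride + 1L else 0L
  if (n == 0L) {
    warning("record '", record@subjectId, "' has ", l,
            " frames (< window ", window, "); no clips extracted")
    data <- array(0, c(3L, window, v, 0L))
    return(methods::new("GaitClipSet", data = data, subjectId = character(0),
                        label = character(0),
                        jointIndices = seq_len(v)))
  }
  data <- array(0, c(3L, as.integer(window), v, n))
  # coords are 3 x V x T; clips are 3 x T x V
  for (j in seq_len(n)) {
    start <- (j - 1L) * stride + 1L
    data[, , , j] <- aperm(record@coords[, , start:(start + window - 1L),
                                         drop = FALSE], c(1L, 3L, 2L))
  }
  methods::new("GaitClipSet", data = data,
               subjectId = rep(record@subjectId, n),
               label = rep(as.character(label), n),
               jointIndices = seq_len(v))
}

#' Restrict clips to a joint subset
#'
#' Keeps only the selected joints (ascending original index order); D and T
#' are unchanged. The retained original indices are recorded in the result's
#' `jointIndices` slot.
#'
#' @param clips a [GaitClipSet-class].
#' @param subset integer vector of 1-based joint indices into the clip's
#'   current joints (interpreted in the original joint indexing).
#' @return a [GaitClipSet-class] with `V = length(subset)` joints.
#' @export
selectJoints <- function(clips, subset = defaultJointSubset()) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) stop("joint subset must be nonempty")
  cur <- clips@jointIndices
  pos <- match(subset, cur)
  if (anyNA(pos))
    stop("joint indices not present in clip set: ",
         paste(subset[is.na(pos)], collapse = ", "))
  methods::new("GaitClipSet",
               data = clips@data[, , pos, , drop = FALSE],
               subjectId = clips@subjectId, label = clips@label,
               jointIndices = cur[pos])
}

#' Combine several clip sets
#'
#' @param ... [GaitClipSet-class] objects over the same joints and window.
#' @return a single [GaitClipSet-class].
#' @export
bindClipSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "GaitClipSet"))
    sets <- sets[[1L]]
  sets <- Filter(function(s) nClips(s) > 0L, sets)
  if (length(sets) == 0L) stop("no non-empty clip sets to combine")
  d1 <- dim(sets[[1L]]@data)[1:3]
  for (s in sets) {
    if (!identical(dim(s@data)[1:3], d1) ||
        !identical(s@jointIndices, sets[[1L]]@jointIndices))
      stop("clip sets have incompatible shapes or joint subsets")
  }
  n <- sum(vapply(sets, nClips, integer(1)))
  data <- array(0, c(d1, n))
  at <- 0L
  for (s in sets) {
    k <- nClips(s)
    data[, , , at + seq_len(k)] <- s@data
    at <- at + k
  }
  methods::new("GaitClipSet", data = data,
               subjectId = unlist(lapply(sets, function(s) s@subjectId)),
               label = unlist(lapply(sets, function(s) s@label)),
               jointIndices = sets[[1L]]@jointIndices)
}
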