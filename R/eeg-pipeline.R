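#' @include AllClasses.R
NULL

#' The 64 electrode labels of the extended 10-20 montage
#'
#' 62 scalp electrodes plus the `Ref` and `Gnd` electrodes that are removed
#' by common-average re-referencing. Shipped as
#' `inst/extdata/eeg_channels_1020.txt`.
#'
#' @return character vector of length 64.
#' @export
eegChannelLabels64 <- function() {
  path <- system.file("extdata", "eeg_channels_1020.txt",
                      package = "adcascade")
  readLines(path)
}

#' Construct an EEGRecord
#'
#' @param subjectId character scalar.
#' @param data numeric channels x samples matrix in microvolts.
#' @param samplingRate sampling frequency in Hz.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param channelLabels one label per row of `data`.
#' @return an [EEGRecord-class].
#' @export
eegRecord <- function(subjectId, data, samplingRate,
                      condition = "eyes_open",
                      channelLabels = eegChannelLabels64()) {
  methods::new("EEGRecord", subjectId = as.character(subjectId),
               condition = condition, channelLabels = channelLabels,
               samplingRate = samplingRate, data = data)
}

#' Common-average re-referencing
#'
#' Drops the reference and ground channels, then subtracts from every
#' remaining channel, at each time sample, the mean over the remaining
#' channels. A 64-channel recording becomes 62 channels whose per-sample
#' mean is zero. Applying the operation again (once Ref/Gnd are gone) is a
#' no-op up to floating-point error.
#'
#' @param record an [EEGRecord-class].
#' @param refLabels labels of the channels to remove before averaging
#'   (default `c("Ref", "Gnd")`; configurable aliases).
#' @return the re-referenced [EEGRecord-class] with
#'   `length(refLabels)` fewer channels.
#' @export
rereferenceCommonAverage <- function(record, refLabels = c("Ref", "Gnd")) {
  hit <- match(refLabels, record@channelLabels)
  if (anyNA(hit))
    stop("channel label(s) not found: ",
         paste(refLabels[is.na(hit)], collapse = ", "),
         " (use refLabels= to name the reference/ground channels)")
  keep <- setdiff(seq_along(record@channelLabels), hit)
  x <- record@data[keep, , drop = FALSE]
  x <- sweep(x, 2L, colMeans(x))
  methods::initialize(record, data = x,
                      channelLabels = record@channelLabels[keep])
}

# Hamming-windowed sinc low-pass, normalized to exact unit DC gain.
firLowpass <- function(cutoff, taps) {
  stopifnot(taps %% 2L == 1L)
  m <- (taps - 1L) / 2
  n <- seq(-m, m)
  h <- 2 * cutoff * sinc(2 * cutoff * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase FIR filtering with reflection padding at the edges.
filterZeroPhase <- function(x, h) {
  m <- (length(h) - 1L) / 2L
  n <- length(x)
  pad <- c(x[(m + 1L):2L], x, x[(n - 1L):(n - m)])
  y <- stats::filter(pad, h, sides = 2L)
  as.numeric(y[(m + 1L):(m + n)])
}

#' Anti-aliased downsampling of an EEG record
#'
#' Low-pass filters each channel with a zero-phase FIR filter (cutoff at
#' 80% of the target Nyquist frequency) and decimates by the integer factor
#' `samplingRate / targetRate`. The sample count is divided by the factor
#' (floor); a factor of one returns the record unchanged.
#'
#' @param record an [EEGRecord-class].
#' @param targetRate target sampling rate in Hz (default 250); must divide
#'   the record's sampling rate.
#' @return the downsampled [EEGRecord-class].
#' @export
downsampleRecord <- function(record, targetRate = 250) {
  q <- record@samplingRate / targetRate
  if (abs(q - round(q)) > 1e-9)
    stop("sampling rate ", record@samplingRate,
         " is not an integer multiple of the target rate ", targetRate)
  q <- as.integer(round(q))
  if (q == 1L) return(record)
  h <- firLowpass(0.4 / q, taps = 10L * q + 1L)   # 0.8 * Nyquist/q
  x <- record@data
  keep <- seq(1L, ncol(x), by = q)
  y <- matrix(0, nrow(x), length(keep))
  for (ch in seq_len(nrow(x))) {
    y[ch, ] <- filterZeroPhase(x[ch, ], h)[keep]
  }
  methods::initialize(record, data = y, samplingRate = targetRate)
}

#' Cut paired eyes-open/eyes-closed epochs
#'
#' Slides a non-overlapping window of `window` samples over each condition;
#' the i-th window of the eyes-open record is concatenated in time with the
#' i-th window of the eyes-closed record, giving a `C x 2*window` plane
#' that is depth-replicated to `3 x C x 2*window` at model-input time.
#' Exactly `epochsPerSubject` index-aligned pairs are emitted: the first
#' ones in temporal order by default, or a seeded random selection.
#'
#' @param open,closed re-referenced, downsampled [EEGRecord-class] objects
#'   of the two conditions, same channel order.
#' @param window per-condition window length in samples (default 256,
#'   about one second at 250 Hz).
#' @param epochsPerSubject number of epochs to emit (default 120).
#' @param label optional stage-2 label (`"MCI"` or `"AD"`).
#' @param selection `"first"` (deterministic) or `"random"`.
#' @param seed seed for `selection = "random"`.
#' @return an [EEGEpochSet-class].
#' @export
extractEpochs <- function(open, closed, window = 256L,
                          epochsPerSubject = 120L, label = NA,
                          selection = c("first", "random"), seed = NULL) {
  selection <- match.arg(selection)
  if (open@subjectId != closed@subjectId)
    stop("records belong to different subjects")
  if (!identical(open@channelLabels, closed@channelLabels))
    stop("channel order differs between conditions")
  availOpen <- ncol(open@data) %/% window
  availClosed <- ncol(closed@data) %/% window
  avail <- min(availOpen, availClosed)
  if (avail < epochsPerSubject)
    stop("subject '", open@subjectId, "': only ", avail,
         " non-overlapping windows available per condition (",
         epochsPerSubject, " requested)")
  idx <- if (selection == "first") seq_len(epochsPerSubject)
         else withSeed(seed, sort(sample.int(avail, epochsPerSubject)))
  c0 <- nrow(open@data)
  data <- array(0, c(c0, 2L * window, length(idx)))
  for (j in seq_along(idx)) {
    s <- (idx[j] - 1L) * window
    data[, seq_len(window), j] <- open@data[, s + seq_len(window)]
    data[, window + seq_len(window), j] <- closed@data[, s + seq_len(window)]
  }
  methods::new("EEGEpochSet", data = data,
               subjectId = rep(open@subjectId, length(idx)),
               label = rep(as.character(label), length(idx)),
               window = as.integer(window),
               channelLabels = open@channelLabels)
}

#' Combine several epoch sets
#'
#' @param ... [EEGEpochSet-class] objects with identical channels/window,
#'   or a single list of them.
#' @return a single [EEGEpochSet-class].
#' @export
bindEpochSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !is(sets[[1L]], "EEGEpochSet"))
    sets <- sets[[1L]]
  stopifnot(length(sets) > 0L)
  d1 <- dim(sets[[1L]]@data)[1:2]
  for (s in sets) {
    if (!identical(dim(s@data)[1:2], d1))
      stop("epoch sets have incompatible shapes")
  }
  n <- sum(vapply(sets, nEpochs, integer(1)))
  data <- array(0, c(d1, n))
  at <- 0L
  for (s in sets) {
    k <- nEpochs(s)
    if (k > 0) data[, , at + seq_len(k)] <- s@data
    at <- at + k
  }
  methods::new("EEGEpochSet", data = data,
               subjectId = unlist(lapply(sets, function(s) s@subjectId)),
               label = unlist(lapply(sets, function(s) s@label)),
               window = sets[[1L]]@window,
               channelLabels = sets[[1L]]@channelLabels)
}

#' Subset an epoch set by epoch index
#'
#' @param epochs an [EEGEpochSet-class].
#' @param idx integer epoch indices.
#' @return an [EEGEpochSet-class] with the selected epochs.
#' @export
subsetEpochs <- function(epochs, idx) {
  methods::new("EEGEpochSet",
               data = epochs@data[, , idx, drop = FALSE],
               subjectId = epochs@subjectId[idx],
               label = epochs@label[idx],
               window = epochs@window,
               channelLabels = epochs@channelLabels)
}

#' Random epoch-wise train/test split
#'
#' Partitions epochs uniformly at random without replacement:
#' `round(trainFraction * N)` epochs train, the rest test; disjoint,
#' exhaustive and reproducible for a given seed. Note that an epoch-wise
#' split places epochs of the same subject on both sides; a subject-wise
#' split (see `by = "subject"`) avoids that identity leakage and is the
#' recommended protocol for honest generalization estimates.
#'
#' @param epochs an [EEGEpochSet-class].
#' @param trainFraction fraction assigned to training (strictly between 0
#'   and 1; default 0.75).
#' @param seed integer seed.
#' @param by `"epoch"` (default) or `"subject"` (keeps each subject's
#'   epochs on one side; the fraction then applies to subjects).
#' @return list with elements `train` and `test`, both
#'   [EEGEpochSet-class] objects.
#' @export
splitEpochs <- function(epochs, trainFraction = 0.75, seed = 1L,
                        by = c("epoch", "subject")) {
  by <- match.arg(by)
  stopifnot(trainFraction > 0, trainFraction < 1)
  n <- nEpochs(epochs)
  if (n == 0L) stop("cannot split an empty epoch set")
  trainIdx <- if (by == "epoch") {
    k <- round(trainFraction * n)
    withSeed(seed, sample.int(n, k))
  } else {
    subj <- unique(epochs@subjectId)
    k <- round(trainFraction * length(subj))
    pick <- withSeed(seed, sample(subj, k))
    which(epochs@subjectId %in% pick)
  }
  list(train = subsetEpochs(epochs, sort(trainIdx)),
       test = subsetEpochs(epochs, sort(setdiff(seq_len(n), trainIdx))))
}
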