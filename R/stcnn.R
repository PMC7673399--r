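#' @include nn-core.R AllClasses.R
NULL

#' Configuration of the stage-2 EEG classifier
#'
#' The default layer plan is: input batch normalization over the 3 depth
#' planes, then four spatial-temporal modules
#' (3->4, Ks=1, Kt=33, stride 1), (4->4, Ks=15, Kt=33, stride 4),
#' (4->16, Ks=C, Kt=33, stride 1), (16->8, Ks=1, Kt=33, stride 4),
#' then flatten, a fully connected layer and softmax. `Ks` convolves across
#' electrodes (same-padded, except `Ks = C` which is a valid convolution and
#' collapses the electrode extent to 1) and `Kt` across time samples
#' (same-padded; the stride applies to the time axis only). On the default
#' `3 x 62 x 512` epoch the flattened feature has length
#' `8 * 512/16 = 256`.
#'
#' @param C number of EEG channels after re-referencing (default 62).
#' @param timeExtent concatenated epoch length 2T (default 512).
#' @param nClasses number of output classes (2: MCI vs AD).
#' @param plan data.frame with columns `inCh`, `outCh`, `ks`, `kt`,
#'   `stride`; one row per module.
#' @return list of class `"stCnnConfig"`.
#' @export
stCnnConfig <- function(C = 62L, timeExtent = 512L, nClasses = 2L,
                        plan = NULL) {
  if (is.null(plan)) {
    plan <- data.frame(inCh = c(3L, 4L, 4L, 16L),
                       outCh = c(4L, 4L, 16L, 8L),
                       ks = c(1L, 15L, as.integer(C), 1L),
                       kt = c(33L, 33L, 33L, 33L),
                       stride = c(1L, 4L, 1L, 4L))
  }
  structure(list(C = as.integer(C), timeExtent = as.integer(timeExtent),
                 nClasses = as.integer(nClasses), plan = plan),
            class = "stCnnConfig")
}

# Shape arithmetic for a module sequence; errors early on impossible plans.
stCnnShapes <- function(config) {
  h <- config$C
  w <- config$timeExtent
  shapes <- list()
  for (r in seq_len(nrow(config$plan))) {
    p <- config$plan[r, ]
    if (p$ks > h)
      stop("module ", r, ": spatial kernel ", p$ks,
           " exceeds electrode extent ", h)
    h <- if (p$ks == h) 1L else h                     # valid vs same-padded
    w <- (w + 2L * ((p$kt - 1L) %/% 2L) - p$kt) %/% p$stride + 1L
    shapes[[r]] <- c(p$outCh, h, w)
  }
  shapes
}

#' Initialize the stage-2 ST-CNN model
#'
#' @param config an [stCnnConfig()] list.
#' @param seed integer seed for weight initialization.
#' @return an [StCnnModel-class].
#' @export
stCnnModel <- function(config = stCnnConfig(), seed = 1L) {
  stopifnot(inherits(config, "stCnnConfig"))
  shapes <- stCnnShapes(config)
  last <- shapes[[length(shapes)]]
  flat <- prod(last)
  layers <- withSeed(seed, {
    ls <- list(nnBN(config$plan$inCh[1L]))
    h <- config$C
    for (r in seq_len(nrow(config$plan))) {
      p <- config$plan[r, ]
      samePad <- p$ks < h
      ls[[length(ls) + 1L]] <- nnConv(p$inCh, p$outCh, p$ks, 1L,
                                      ph = if (samePad) (p$ks - 1L) %/% 2L
                                           else 0L)
      ls[[length(ls) + 1L]] <- nnConv(p$outCh, p$outCh, 1L, p$kt,
                                      sw = p$stride,
                                      pw = (p$kt - 1L) %/% 2L)
      ls[[length(ls) + 1L]] <- nnBN(p$outCh)
      ls[[length(ls) + 1L]] <- nnELU()
      h <- if (p$ks == h) 1L else h
    }
    ls[[length(ls) + 1L]] <- nnFlatten()
    ls[[length(ls) + 1L]] <- nnFC(flat, config$nClasses)
    ls
  })
  cfg <- unclass(config)
  cfg$flattenLength <- flat
  methods::new("StCnnModel", config = cfg, layers = layers,
               classes = STAGE2_CLASSES)
}

#' Flattened feature length of an ST-CNN model
#'
#' @param model an [StCnnModel-class].
#' @return integer: the length of the feature vector entering the
#'   classification head (256 under the default plan).
#' @export
flattenLength <- function(model) model@config$flattenLength

#' Per-epoch class scores of the EEG model
#'
#' Depth-replicates each stored epoch plane to the `3 x C x 2T` input,
#' runs the network in evaluation mode and returns softmax scores
#' (rows MCI, AD), one column per epoch.
#'
#' @param model an [StCnnModel-class].
#' @param epochs an [EEGEpochSet-class] or a `3 x C x 2T (x N)` array.
#' @param batchSize evaluation batch size (memory knob only).
#' @return numeric `nClasses x N` score matrix.
#' @export
stCnnForward <- function(model, epochs, batchSize = 64L) {
  x <- if (is(epochs, "EEGEpochSet")) replicateEpochPlanes(epochs@data)
       else epochs
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[2L] != model@config$C || d[3L] != model@config$timeExtent)
    stop(sprintf("epoch shape %d x %d x %d does not match expected 3 x %d x %d",
                 d[1L], d[2L], d[3L], model@config$C,
                 model@config$timeExtent))
  predictScoresLayers(model@layers, x, batchSize)
}

# (C, 2T, N) single plane -> (3, C, 2T, N) replicated tensor batch
replicateEpochPlanes <- function(plane) {
  d <- dim(plane)
  x <- array(0, c(3L, d))
  x[1L, , , ] <- plane
  x[2L, , , ] <- plane
  x[3L, , , ] <- plane
  x
}

#' One spatial-temporal convolution module (functional form)
#'
#' A spatial convolution with kernel `ks x 1` along the electrode axis
#' (same-padded, unless `ks` equals the electrode extent, which is a valid
#' convolution collapsing the extent to 1) followed by a temporal
#' convolution with kernel `1 x kt` along time (same-padded, stride on the
#' time axis). Feature channels go `inCh -> outCh` on the spatial
#' convolution. This functional form is the bare two-convolution module;
#' inside the model each module is followed by batch normalization and an
#' exponential-linear nonlinearity.
#'
#' @param x numeric `inCh x C x time (x N)` array.
#' @param inCh,outCh channel counts.
#' @param ks,kt spatial/temporal kernel sizes.
#' @param stride temporal stride.
#' @param weights optional list with `spatialW` (`inCh x ks x outCh`),
#'   `spatialB` (`outCh`), `temporalW` (`outCh x kt x outCh`), `temporalB`
#'   (`outCh`); randomly initialized when omitted.
#' @param seed seed used when `weights` is omitted.
#' @return list with `y` (the output array) and `weights` (as used).
#' @export
stCnnModule <- function(x, inCh, outCh, ks, kt, stride = 1L,
                        weights = NULL, seed = 1L) {
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  h <- dim(x)[2L]
  if (ks > h)
    stop("spatial kernel ", ks, " exceeds electrode extent ", h)
  if (is.null(weights)) {
    weights <- withSeed(seed, list(
      spatialW = array(heInit(inCh * ks, inCh * ks * outCh),
                       c(inCh, ks, outCh)),
      spatialB = numeric(outCh),
      temporalW = array(heInit(outCh * kt, outCh * kt * outCh),
                        c(outCh, kt, outCh)),
      temporalB = numeric(outCh)))
  }
  convS <- nnConv(inCh, outCh, ks, 1L,
                  ph = if (ks < h) (ks - 1L) %/% 2L else 0L)
  convS$params$W <- matrix(weights$spatialW, inCh * ks, outCh)
  convS$params$b <- weights$spatialB
  convT <- nnConv(outCh, outCh, 1L, kt, sw = as.integer(stride),
                  pw = (kt - 1L) %/% 2L)
  convT$params$W <- matrix(weights$temporalW, outCh * kt, outCh)
  convT$params$b <- weights$temporalB
  y <- nnForward(convT, nnForward(convS, x)$y)$y
  if (squeeze) dim(y) <- dim(y)[-4L]
  list(y = y, weights = weights)
}
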