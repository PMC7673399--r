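#' @include skeleton-graph.R nn-core.R
NULL

#' Configuration of the stage-1 gait classifier
#'
#' The default backbone is the ten-block plan of the reference
#' spatial-temporal graph-convolution architecture: channels
#' (64,64,64,64,128,128,128,256,256,256) with temporal kernel 9 and temporal
#' stride 2 at blocks 5 and 8, one hourglass attention module after block 9,
#' and a two-class softmax head. Smaller plans are accepted for desk-scale
#' experiments; the attention placement must stay within the block count.
#'
#' @param channels integer vector of per-block output channels.
#' @param strides integer vector of per-block temporal strides (same
#'   length as `channels`).
#' @param tKernel temporal kernel length (odd; default 9).
#' @param attention one of `"none"`, `"after-3"`, `"after-6"`, `"after-9"`,
#'   `"all"` (= after blocks 3, 6 and 9), or an integer vector of block
#'   positions.
#' @param dropout dropout rate inside blocks (default 0.5).
#' @param nClasses number of output classes (2: HC vs patient).
#' @param jointSubset 1-based joint indices of the key-point subset, or
#'   `NULL` for the full 25-joint skeleton.
#' @param attentionKernel temporal kernel of the attention downsampling
#'   convolutions (default 5).
#' @return list of class `"astGcnConfig"`.
#' @export
astGcnConfig <- function(channels = c(64, 64, 64, 64, 128, 128, 128,
                                      256, 256, 256),
                         strides = c(1, 1, 1, 1, 2, 1, 1, 2, 1, 1),
                         tKernel = 9L,
                         attention = "after-9",
                         dropout = 0.5,
                         nClasses = 2L,
                         jointSubset = defaultJointSubset(),
                         attentionKernel = 5L) {
  stopifnot(length(channels) == length(strides), tKernel %% 2 == 1)
  nb <- length(channels)
  att <- if (is.numeric(attention)) {
    as.integer(attention)
  } else {
    switch(attention,
           none = integer(0),
           "after-3" = 3L, "after-6" = 6L, "after-9" = 9L,
           all = c(3L, 6L, 9L),
           stop("unknown attention placement: ", attention))
  }
  if (any(att < 1L | att > nb))
    stop("attention placement outside the ", nb, "-block plan")
  structure(list(channels = as.integer(channels),
                 strides = as.integer(strides),
                 tKernel = as.integer(tKernel),
                 attention = if (is.numeric(attention))
                   paste0("after-", paste(att, collapse = ","))
                 else attention,
                 attentionAt = att,
                 dropout = dropout, nClasses = as.integer(nClasses),
                 jointSubset = jointSubset,
                 attentionKernel = as.integer(attentionKernel)),
            class = "astGcnConfig")
}

#' Initialize the stage-1 AST-GCN model
#'
#' Builds the (key-point) skeleton graph, its spatial-configuration
#' partition, and the layer stack: input batch normalization, the
#' spatial-temporal graph-convolution blocks (each with its own learnable
#' edge-importance masks, initialized to ones), hourglass attention at the
#' configured placements, global average pooling over frames and joints,
#' and the softmax classification head.
#'
#' @param config an [astGcnConfig()] list.
#' @param graph optional [SkeletonGraph-class]; by default the Kinect V2
#'   skeleton restricted to `config$jointSubset` (with bridge edges).
#' @param seed integer seed for weight initialization.
#' @return an [AstGcnModel-class].
#' @export
astGcnModel <- function(config = astGcnConfig(), graph = NULL, seed = 1L) {
  stopifnot(inherits(config, "astGcnConfig"))
  if (is.null(graph)) {
    full <- buildSkeletonGraph(kinectEdges(), 25L, 1L)
    graph <- if (is.null(config$jointSubset)) full
             else inducedSkeletonGraph(full, config$jointSubset)
  }
  parts <- partitionSpatialConfiguration(graph)
  layers <- withSeed(seed, {
    ls <- list(nnBN(3L))
    cin <- 3L
    for (b in seq_along(config$channels)) {
      cout <- config$channels[b]
      ls[[length(ls) + 1L]] <- nnSTGCNBlock(
        cin, cout, parts@normalized, tKernel = config$tKernel,
        stride = config$strides[b], dropout = config$dropout,
        residual = b > 1L)
      if (b %in% config$attentionAt)
        ls[[length(ls) + 1L]] <- nnAttention(cout, config$attentionKernel)
      cin <- cout
    }
    ls[[length(ls) + 1L]] <- nnGAPool()
    ls[[length(ls) + 1L]] <- nnFC(cin, config$nClasses)
    ls
  })
  methods::new("AstGcnModel", config = unclass(config), layers = layers,
               graph = graph, partitions = parts, classes = STAGE1_CLASSES)
}

#' @describeIn parameterCount learnable scalars of the gait model.
#' @export
setMethod("parameterCount", "AstGcnModel",
          function(model) nnParamCount(model@layers))

#' @describeIn parameterCount learnable scalars of the EEG model.
#' @export
setMethod("parameterCount", "StCnnModel",
          function(model) nnParamCount(model@layers))

#' Per-clip class scores of the gait model
#'
#' Runs the network in evaluation mode (running batch-norm statistics, no
#' dropout) and returns softmax scores. Scores sum to one per clip; clips
#' are processed independently, so batching does not affect results.
#'
#' @param model an [AstGcnModel-class].
#' @param clips a [GaitClipSet-class] or a `3 x T x V (x N)` array over the
#'   model's joints.
#' @param batchSize evaluation batch size (memory knob only).
#' @return numeric `nClasses x N` matrix of scores; rows named by class.
#' @export
astGcnForward <- function(model, clips, batchSize = 64L) {
  x <- if (is(clips, "GaitClipSet")) clips@data else clips
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3L] != model@graph@V)
    stop("clip joint count ", dim(x)[3L], " does not match the model graph (",
         model@graph@V, " joints)")
  predictScoresLayers(model@layers, x, batchSize)
}

predictScoresLayers <- function(layers, x, batchSize = 64L,
                                classes = NULL) {
  n <- dim(x)[length(dim(x))]
  out <- NULL
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    f <- nnModelForward(layers, sliceLast(x, idx), training = FALSE)
    p <- softmaxProbs(f$y)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}

#' Partitioned spatial graph convolution (single layer, functional form)
#'
#' Computes `f_out = sum_k Lambda^{-1/2} (B_k (*) M_k) Lambda^{-1/2} f_in W_k`
#' over the three spatial-configuration subsets, where `(*)` is the
#' elementwise product with the learnable edge-importance mask. With all
#' masks at one this reduces to the unmasked normalized-adjacency form.
#' The operation acts per frame: no temporal mixing.
#'
#' @param features numeric `C_in x T x V` (or `C_in x T x V x N`) array.
#' @param partitions a [PartitionedAdjacency-class].
#' @param weights numeric `C_in x C_out x 3` array of subset weights.
#' @param masks numeric `V x V x 3` edge-importance masks (default all
#'   ones).
#' @return array `C_out x T x V (x N)`.
#' @export
spatialGraphConv <- function(features, partitions, weights, masks = NULL) {
  d <- dim(features)
  squeeze <- length(d) == 3L
  if (squeeze) dim(features) <- c(d, 1L)
  v <- dim(features)[3L]
  if (nrow(partitions@normalized[[1L]]) != v)
    stop("feature joint axis does not match the partition size")
  if (is.null(masks)) masks <- array(1, c(v, v, 3L))
  stopifnot(dim(weights)[1L] == dim(features)[1L], dim(weights)[3L] == 3L)
  layer <- list(type = "graphconv",
                params = list(W = weights, M = masks),
                ahat = partitions@normalized)
  y <- nnForward(layer, features, training = FALSE)$y
  if (squeeze) dim(y) <- dim(y)[1:3]
  y
}

#' Hourglass attention module (functional form)
#'
#' The mask branch compresses the temporal axis with two stride-4
#' convolutions (T to T/4 to T/16), restores it with two nearest-neighbour
#' upsampling steps, and produces a sigmoid gate `g` via a 1x1 convolution;
#' the output is `features * (1 + g)`, so every output magnitude lies
#' between 1x and 2x the trunk feature. Inputs whose temporal extent is not
#' a multiple of 16 are zero-padded internally and cropped back.
#'
#' @param features numeric `C x T x V (x N)` array.
#' @param module a module created by [hourglassModule()]; a fresh seeded
#'   module is created when omitted.
#' @return array of the same shape as `features`.
#' @export
hourglassAttention <- function(features, module = NULL) {
  d <- dim(features)
  squeeze <- length(d) == 3L
  if (squeeze) dim(features) <- c(d, 1L)
  if (is.null(module)) module <- hourglassModule(dim(features)[1L])
  y <- nnForward(module, features, training = FALSE)$y
  if (squeeze) dim(y) <- dim(y)[1:3]
  y
}

#' Create an hourglass attention module
#'
#' @param channels feature channel count C.
#' @param kernel temporal kernel of the downsampling convolutions.
#' @param seed seed for weight initialization.
#' @return an opaque module usable with [hourglassAttention()].
#' @export
hourglassModule <- function(channels, kernel = 5L, seed = 1L) {
  withSeed(seed, nnAttention(as.integer(channels), as.integer(kernel)))
}

# Evaluate expr with a local, restored RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
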