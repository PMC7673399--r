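#' @include nn-core.R
NULL

#' Subject identifier of an object
#'
#' @param x an object carrying a subject identifier.
#' @return A character scalar (or vector, for clip/epoch sets with one entry
#'   per item).
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Group label(s) carried by an object
#'
#' @param x an object carrying diagnostic group labels.
#' @return Character labels among `"HC"`, `"MCI"`, `"AD"` (stage-specific
#'   objects may use `"PATIENT"`), possibly `NA` when unknown.
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' Sampling rate in Hz
#'
#' @param x an object with a time base.
#' @return A numeric scalar, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel labels of a recording
#'
#' @param x an object with labelled channels.
#' @return Character vector of channel labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Number of learnable scalars in a model
#'
#' Counts every learnable parameter entry (convolution kernels, biases,
#' batch-norm scale/shift, edge-importance masks, classifier weights).
#' The count is a property of the architecture and does not depend on
#' training or evaluation mode.
#'
#' @param model a fitted or freshly initialized model object.
#' @return Integer-valued numeric scalar.
#' @export
setGeneric("parameterCount", function(model) standardGeneric("parameterCount"))
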