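#' @include RcppExports.R
NULL

#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @export
setGeneric("trialLink", function(x) standardGeneric("trialLink"))

#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @export
setGeneric("slopeValues", function(x) standardGeneric("slopeValues"))

#' @export
setGeneric("interceptValues", function(x) standardGeneric("interceptValues"))

#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @export
setGeneric("componentLoadings", function(x, rotated = TRUE, standardized = FALSE)
  standardGeneric("componentLoadings"))

#' @export
setGeneric("retainedComponents", function(x) standardGeneric("retainedComponents"))

#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))
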