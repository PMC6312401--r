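#' @rdname EpochsArray-class
#' @param object,x an \linkS4class{EpochsArray} (or other package object).
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EpochsArray-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname EpochsArray-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname EpochsArray-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EpochsArray-class
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname EpochsArray-class
#' @export
setGeneric("rejectedTrials", function(x) standardGeneric("rejectedTrials"))

#' @rdname EpochsArray-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EpochsArray-class
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' @rdname EpochsArray-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname ChannelResponseTensor-class
#' @export
setGeneric("channelResponses", function(x) standardGeneric("channelResponses"))

#' @rdname ChannelResponseTensor-class
#' @export
setGeneric("isCentered", function(x) standardGeneric("isCentered"))

#' @rdname ChannelResponseTensor-class
#' @export
setGeneric("channelOffsets", function(x) standardGeneric("channelOffsets"))
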