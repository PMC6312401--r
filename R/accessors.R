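#' @rdname EpochsArray-class
#' @export
setMethod("epochData", "EpochsArray", function(x) x@data)

#' @rdname EpochsArray-class
#' @export
setMethod("sampleRate", "EpochsArray", function(x) x@sampleRate)

#' @rdname EpochsArray-class
#' @export
setMethod("timePoints", "EpochsArray", function(x)
  x@t0 + (seq_len(dim(x@data)[3L]) - 1L) / x@sampleRate)

#' @rdname EpochsArray-class
#' @export
setMethod("channelLabels", "EpochsArray", function(x) x@channelLabels)

#' @rdname EpochsArray-class
#' @export
setMethod("designTable", "EpochsArray", function(x) x@design)

#' @rdname EpochsArray-class
#' @export
setMethod("rejectedTrials", "EpochsArray", function(x) x@rejected)

#' @rdname EpochsArray-class
#' @export
setMethod("nTrials", "EpochsArray", function(x) dim(x@data)[1L])

#' @rdname EpochsArray-class
#' @export
setMethod("nSensors", "EpochsArray", function(x) dim(x@data)[2L])

#' @rdname EpochsArray-class
#' @export
setMethod("nSamples", "EpochsArray", function(x) dim(x@data)[3L])

setMethod("show", "EpochsArray", function(object) {
  d <- dim(object@data)
  tp <- timePoints(object)
  cat(sprintf("EpochsArray: %d trials x %d sensors x %d samples\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  time %.3f .. %.3f s @ %g Hz; %d rejected trial(s)\n",
              tp[1L], tp[length(tp)], object@sampleRate,
              sum(object@rejected)))
  if ("condition" %in% names(object@design)) {
    tab <- table(object@design$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @rdname ChannelResponseTensor-class
#' @param object,x a \linkS4class{ChannelResponseTensor}.
#' @export
setMethod("channelResponses", "ChannelResponseTensor", function(x) x@responses)

#' @rdname ChannelResponseTensor-class
#' @export
setMethod("isCentered", "ChannelResponseTensor", function(x) x@centered)

#' @rdname ChannelResponseTensor-class
#' @export
setMethod("channelOffsets", "ChannelResponseTensor", function(x) x@offsets)

#' @rdname ChannelResponseTensor-class
#' @export
setMethod("timePoints", "ChannelResponseTensor", function(x) x@timeAxis)

#' @rdname ChannelResponseTensor-class
#' @export
setMethod("designTable", "ChannelResponseTensor", function(x) x@design)

#' @rdname ChannelResponseTensor-class
#' @export
setMethod("nTrials", "ChannelResponseTensor", function(x) dim(x@responses)[1L])

setMethod("show", "ChannelResponseTensor", function(object) {
  d <- dim(object@responses)
  cat(sprintf("ChannelResponseTensor: %d trials x %d channels x %d times (%s)\n",
              d[1L], d[2L], d[3L],
              if (object@centered) "centered" else "uncentered"))
  invisible(NULL)
})

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet: %d half-cosine^%d channels at %s degrees\n",
              length(object@centers), object@exponent,
              paste(object@centers, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "GeneralizationMap", function(object) {
  cat(sprintf("GeneralizationMap: %d train x %d test time points\n",
              length(object@trainTimes), length(object@testTimes)))
  invisible(NULL)
})
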