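#' @import methods
NULL

ORIENTATION_GRID <- seq(0, 160, by = 20)

#' EpochsArray: epoched multichannel EEG
#'
#' Container for epoched EEG: a trials x sensors x samples tensor in
#' microvolts, a uniform time axis, sensor labels, the per-trial design
#' table, and a rejection mask. The time axis is anchored at the onset of
#' the first stimulus of each trial; sample \code{i} occurs at
#' \code{t0 + (i - 1) / sampleRate} seconds.
#'
#' @slot data numeric array \code{[n_trials, n_sensors, n_samples]}, microvolts.
#' @slot sampleRate sampling rate in Hz.
#' @slot t0 time of the first sample in seconds relative to first-stimulus onset.
#' @slot channelLabels character vector of sensor labels (10-20 style).
#' @slot design \code{data.frame} of per-trial records, aligned row-for-row
#'   with the first dimension of \code{data}.
#' @slot rejected logical per-trial rejection mask (TRUE = excluded downstream).
#'
#' @seealso [simulateEpochs()], [readEpochs()], [rereferenceCommonAverage()]
#' @export
setClass("EpochsArray",
  slots = c(
    data          = "array",
    sampleRate    = "numeric",
    t0            = "numeric",
    channelLabels = "character",
    design        = "data.frame",
    rejected      = "logical"
  )
)

setValidity("EpochsArray", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3L)
    msg <- c(msg, "data must be a 3-d array [trials x sensors x samples]")
  else {
    if (nrow(object@design) != dim(d)[1L])
      msg <- c(msg, sprintf("design has %d rows but data has %d trials",
                            nrow(object@design), dim(d)[1L]))
    if (length(object@channelLabels) != dim(d)[2L])
      msg <- c(msg, sprintf("%d channel labels for %d sensors",
                            length(object@channelLabels), dim(d)[2L]))
    if (length(object@rejected) != dim(d)[1L])
      msg <- c(msg, "rejected mask length must equal trial count")
    if (!all(is.finite(d)))
      msg <- c(msg, "data contains non-finite values")
  }
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' BasisSet: half-cosine orientation basis
#'
#' A set of non-negative, 180-degree-periodic orientation tuning profiles.
#' Channel \code{i} evaluates to \code{cos(pi * d_i / 180)^exponent}, with
#' \code{d_i} the circular orientation distance (on the 180 degree space)
#' between the stimulus orientation and the channel centre. With 9 channels
#' and exponent 8 the across-channel sum is the constant 315/128 for every
#' orientation, so the basis tiles orientation space without bias.
#'
#' @slot centers channel centre orientations in degrees.
#' @slot exponent even integer power applied to the half cosine.
#' @seealso [makeBasis()], [evalBasis()]
#' @export
setClass("BasisSet",
  slots = c(centers = "numeric", exponent = "integer")
)

setValidity("BasisSet", function(object) {
  msg <- character()
  if (length(object@centers) < 2L)
    msg <- c(msg, "need at least 2 channels")
  if (object@exponent < 2L || object@exponent %% 2L != 0L)
    msg <- c(msg, "exponent must be an even integer >= 2 (odd powers break 180-degree periodicity)")
  if (length(msg)) msg else TRUE
})

#' ChannelResponseTensor: reconstructed channel responses
#'
#' Trial-wise channel responses reconstructed by inverting the encoding
#' model: a trials x channels x time tensor. When \code{centered}, each
#' trial's 9-vector has been circularly shifted so the presented orientation
#' sits at offset 0 degrees (the middle index), and \code{offsets} runs
#' -80 ... +80 in 20 degree steps.
#'
#' @slot responses numeric array \code{[n_trials, n_channels, n_times]}.
#' @slot centered logical; whether responses are orientation-centered.
#' @slot timeAxis time points in seconds (first-stimulus anchored).
#' @slot offsets channel axis: centre orientations (uncentered) or signed
#'   orientation offsets in degrees (centered).
#' @slot design per-trial design table aligned with the first dimension.
#' @export
setClass("ChannelResponseTensor",
  slots = c(
    responses = "array",
    centered  = "logical",
    timeAxis  = "numeric",
    offsets   = "numeric",
    design    = "data.frame"
  )
)

setValidity("ChannelResponseTensor", function(object) {
  msg <- character()
  d <- dim(object@responses)
  if (length(d) != 3L)
    msg <- c(msg, "responses must be [trials x channels x times]")
  else {
    if (length(object@timeAxis) != d[3L])
      msg <- c(msg, "timeAxis length must equal the time dimension")
    if (length(object@offsets) != d[2L])
      msg <- c(msg, "offsets length must equal the channel dimension")
    if (nrow(object@design) != d[1L])
      msg <- c(msg, "design rows must equal the trial dimension")
  }
  if (length(msg)) msg else TRUE
})

#' GeneralizationMap: cross-temporal generalisation of the encoder
#'
#' Orientation selectivity of weights trained at one time point and applied
#' at every other: a train-time x test-time matrix.
#'
#' @slot selectivity numeric matrix \code{[train x test]}.
#' @slot trainTimes training time points, seconds.
#' @slot testTimes test time points, seconds.
#' @export
setClass("GeneralizationMap",
  slots = c(selectivity = "matrix", trainTimes = "numeric", testTimes = "numeric")
)

setValidity("GeneralizationMap", function(object) {
  msg <- character()
  if (nrow(object@selectivity) != length(object@trainTimes))
    msg <- c(msg, "selectivity rows must match trainTimes")
  if (ncol(object@selectivity) != length(object@testTimes))
    msg <- c(msg, "selectivity cols must match testTimes")
  if (!all(is.finite(object@selectivity)))
    msg <- c(msg, "selectivity must be finite")
  if (length(msg)) msg else TRUE
})
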