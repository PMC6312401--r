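replaceData <- function(epochs, data) {
  epochs@data <- data
  epochs
}

sampleWindow <- function(epochs, window) {
  tp <- timePoints(epochs)
  idx <- which(tp >= window[1L] - 1e-9 & tp <= window[2L] + 1e-9)
  if (length(idx) == 0L)
    stop("window [", window[1L], ", ", window[2L],
         "] s contains no samples of the epoch (",
         tp[1L], " .. ", tp[length(tp)], " s)")
  idx
}

#' Re-reference to the common average
#'
#' Subtracts, at every trial and sample, the across-sensor mean from every
#' sensor, so the per-sample sensor mean is exactly zero afterwards.
#' Idempotent.
#'
#' @param epochs an \linkS4class{EpochsArray} with at least 2 sensors.
#' @return the re-referenced \linkS4class{EpochsArray}.
#' @export
rereferenceCommonAverage <- function(epochs) {
  if (nSensors(epochs) < 2L)
    stop("common-average re-referencing needs >= 2 sensors")
  d <- epochs@data
  avg <- colMeans(aperm(d, c(2L, 1L, 3L)))        # trials x samples
  for (s in seq_len(dim(d)[2L])) d[, s, ] <- d[, s, ] - avg
  replaceData(epochs, d)
}

#' Zero-phase Butterworth filtering of epochs
#'
#' Applies a forward-backward (zero-phase) Butterworth filter along the
#' time axis of every trial and sensor: a high-pass when only `lowHz` is
#' given (e.g. the 0.5 Hz drift filter), or a band-pass when both edges are
#' given (e.g. 2-40 Hz for ERP component analysis). Zero-phase filtering is
#' used so component latencies (P1/N1) are not shifted.
#'
#' @param epochs an \linkS4class{EpochsArray}.
#' @param lowHz lower band edge, Hz (>= 0).
#' @param highHz upper band edge, Hz, or `NULL` for a pure high-pass.
#' @param order Butterworth order of the one-pass prototype (default 4;
#'   the effective order doubles with the two passes).
#' @return the filtered \linkS4class{EpochsArray}.
#' @export
filterEpochs <- function(epochs, lowHz, highHz = NULL, order = 4L) {
  nyq <- epochs@sampleRate / 2
  if (lowHz < 0) stop("lowHz must be >= 0")
  if (is.null(highHz)) {
    if (lowHz <= 0 || lowHz >= nyq)
      stop("high-pass edge must lie in (0, Nyquist = ", nyq, ") Hz")
    filt <- signal::butter(order, lowHz / nyq, type = "high")
  } else {
    if (!(lowHz < highHz && highHz < nyq))
      stop("need 0 <= lowHz < highHz < Nyquist = ", nyq, " Hz")
    filt <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  }
  d <- epochs@data
  dm <- dim(d)
  mat <- matrix(aperm(d, c(3L, 1L, 2L)), nrow = dm[3L])
  for (j in seq_len(ncol(mat)))
    mat[, j] <- signal::filtfilt(filt, mat[, j])
  replaceData(epochs, aperm(array(mat, dim = dm[c(3L, 1L, 2L)]),
                            c(2L, 3L, 1L)))
}

#' Baseline correction
#'
#' Subtracts, per trial and sensor, the mean over a baseline window. The
#' window is expressed relative to an anchor: the onset of the second
#' stimulus in the pair (default; the paradigm's -100 to 0 ms baseline) or
#' the first stimulus (control analysis).
#'
#' @param epochs an \linkS4class{EpochsArray}.
#' @param window numeric(2) baseline window in seconds relative to the anchor.
#' @param anchor `"second_gabor"` or `"first_gabor"`.
#' @return the baseline-corrected \linkS4class{EpochsArray}.
#' @export
baselineCorrect <- function(epochs, window = c(-0.1, 0),
                            anchor = c("second_gabor", "first_gabor")) {
  anchor <- match.arg(anchor)
  shift <- if (anchor == "second_gabor") {
    soa <- unique(epochs@design$onset_second_s)
    if (length(soa) != 1L) stop("non-unique second-stimulus onset in design")
    soa
  } else 0
  idx <- sampleWindow(epochs, window + shift)
  d <- epochs@data
  base <- apply(d[, , idx, drop = FALSE], c(1L, 2L), mean)
  replaceData(epochs, d - c(base))   # recycles over the sample dimension
}

#' Threshold-based trial rejection
#'
#' Flags every trial whose absolute peak voltage exceeds the threshold.
#' Retained data values are never altered; the mask accumulates (a trial
#' once rejected stays rejected).
#'
#' @param epochs an \linkS4class{EpochsArray}.
#' @param thresholdUV rejection threshold in microvolts (default 100).
#' @return \linkS4class{EpochsArray} with an updated rejection mask.
#' @export
rejectThreshold <- function(epochs, thresholdUV = 100) {
  if (thresholdUV <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs@data), 1L, max)
  epochs@rejected <- epochs@rejected | (peak > thresholdUV)
  epochs
}

#' Per-condition event-related potentials
#'
#' Averages over trials within each level of a grouping column, then over a
#' sensor subset (e.g. the occipital-parietal cluster). Rejected trials are
#' always excluded; coloured-target trials are excluded by default, as in
#' ERP analyses of the paradigm.
#'
#' @param epochs an \linkS4class{EpochsArray}.
#' @param grouping design column to group by (default `"condition"`).
#' @param sensors character vector of channel labels, or `NULL` for all.
#' @param excludeTargets drop `is_target` trials (default TRUE).
#' @return a list: `time` (seconds), `erp` (groups x samples matrix, uV),
#'   `n` (trial counts per group).
#' @export
conditionERP <- function(epochs, grouping = "condition", sensors = NULL,
                         excludeTargets = TRUE) {
  des <- epochs@design
  gvals <- designFactor(des, grouping)
  if (is.null(sensors)) sidx <- seq_len(nSensors(epochs))
  else {
    sidx <- match(sensors, epochs@channelLabels)
    if (anyNA(sidx))
      stop("unknown sensor label(s): ",
           paste(sensors[is.na(sidx)], collapse = ", "))
  }
  keep <- !epochs@rejected
  if (excludeTargets && "is_target" %in% names(des))
    keep <- keep & !des$is_target
  groups <- sort(unique(gvals))
  erp <- matrix(NA_real_, length(groups), nSamples(epochs),
                dimnames = list(groups, NULL))
  n <- integer(length(groups)); names(n) <- groups
  for (g in groups) {
    tr <- which(keep & gvals == g)
    if (length(tr) == 0L) stop("empty condition cell: ", g)
    n[g] <- length(tr)
    sub <- epochs@data[tr, sidx, , drop = FALSE]
    erp[g, ] <- apply(sub, 3L, mean)
  }
  list(time = timePoints(epochs), erp = erp, n = n)
}

#' Resample epochs to a new rate
#'
#' Linear-interpolation resampling onto a uniform grid at the new rate,
#' preceded by a zero-phase anti-alias low-pass at 0.45 of the new rate
#' when downsampling. Provided for external recordings digitised at higher
#' rates (e.g. 1024 Hz); the simulator generates 256 Hz directly.
#'
#' @param epochs an \linkS4class{EpochsArray}.
#' @param newRate target sampling rate, Hz.
#' @return the resampled \linkS4class{EpochsArray}.
#' @export
resampleEpochs <- function(epochs, newRate) {
  if (newRate <= 0) stop("newRate must be positive")
  if (newRate == epochs@sampleRate) return(epochs)
  if (newRate < epochs@sampleRate)
    epochs <- filterEpochs(epochs, 0.1, 0.45 * newRate)
  tp <- timePoints(epochs)
  newT <- seq(tp[1L], tp[length(tp)], by = 1 / newRate)
  d <- epochs@data
  out <- array(0, dim = c(dim(d)[1:2], length(newT)))
  for (i in seq_len(dim(d)[1L]))
    for (s in seq_len(dim(d)[2L]))
      out[i, s, ] <- stats::approx(tp, d[i, s, ], xout = newT)$y
  epochs@data <- out
  epochs@sampleRate <- newRate
  epochs
}
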