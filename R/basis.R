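#' Signed circular orientation difference on the 180-degree space
#'
#' @param a,b orientations in degrees.
#' @return signed difference in (-90, 90].
#' @keywords internal
orientationDifference <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

# absolute circular orientation distance, [0, 90]
orientationDistance <- function(a, b) abs(orientationDifference(a, b))

#' Construct the half-cosine orientation basis
#'
#' Builds the canonical basis of orientation-selective channels: centres
#' evenly spaced on [0, 180) and a half-cosine profile raised to an even
#' power (8 by default). Each channel peaks at 1 on its centre, falls to 0
#' at 90 degrees away, and the across-channel sum is constant in
#' orientation (315/128 for 9 channels, exponent 8), so the set tiles
#' orientation space evenly.
#'
#' @param nChannels number of channels (default 9, centres 0,20,...,160).
#' @param exponent even integer power (default 8).
#' @return a \linkS4class{BasisSet}.
#' @examples
#' b <- makeBasis()
#' evalBasis(b, 40)           # peaks at the 40-degree channel
#' @export
makeBasis <- function(nChannels = 9L, exponent = 8L) {
  nChannels <- as.integer(nChannels)
  exponent <- as.integer(exponent)
  if (nChannels < 2L) stop("nChannels must be >= 2")
  if (exponent %% 2L != 0L || exponent < 2L)
    stop("exponent must be an even integer >= 2 ",
         "(odd powers break 180-degree periodicity)")
  new("BasisSet", centers = seq(0, 180 - 180 / nChannels,
                                length.out = nChannels),
      exponent = exponent)
}

#' Evaluate basis activations
#'
#' @param basis a \linkS4class{BasisSet}.
#' @param orientations orientations in degrees (any reals; 180-periodic).
#' @return matrix `[n_channels x length(orientations)]` of activations.
#' @export
evalBasis <- function(basis, orientations) {
  d <- outer(basis@centers, orientations, orientationDifference)
  cos(d * pi / 180)^basis@exponent
}

#' Build the tuned design (regression) matrix
#'
#' Column `j` holds the basis activations of trial `j`'s orientation: the
#' presented orientation convolved with the canonical tuning functions.
#' Orientations outside [0, 180) are wrapped modulo 180 with a message.
#'
#' @param orientations per-trial orientations in degrees.
#' @param basis a \linkS4class{BasisSet}.
#' @return numeric matrix `[n_channels x n_trials]`.
#' @export
buildDesignMatrix <- function(orientations, basis = makeBasis()) {
  if (length(orientations) == 0L) stop("empty trial list")
  if (any(orientations < 0 | orientations >= 180)) {
    message("orientations outside [0, 180) wrapped modulo 180")
    orientations <- orientations %% 180
  }
  evalBasis(basis, orientations)
}
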