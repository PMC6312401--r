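#' Estimate encoding weights by least squares
#'
#' Solves `B = W C` for the sensors-by-channels weight matrix `W` by
#' ordinary least squares: `W = B C' (C C')^-1`. `B` holds the sensor data
#' of the training trials (sensors x trials) and `C` the tuned channel
#' responses (channels x trials) from [buildDesignMatrix()].
#'
#' @param B numeric matrix, sensors x training trials.
#' @param C numeric matrix, channels x training trials; must have full row
#'   rank (at least as many distinct orientations as channels).
#' @return the weight matrix, sensors x channels (microvolts per unit
#'   channel activation).
#' @export
fitWeights <- function(B, C) {
  if (ncol(B) != ncol(C))
    stop("B and C must have the same number of trials (columns)")
  if (ncol(C) < nrow(C))
    stop("underdetermined: ", ncol(C), " training trials for ",
         nrow(C), " channels")
  G <- tcrossprod(C)
  kappa <- suppressWarnings(kappa(G, exact = TRUE))
  if (!is.finite(kappa) || kappa > 1e10)
    stop("rank-deficient channel design matrix (condition number ",
         format(kappa, digits = 3), ")")
  t(solve(G, C %*% t(B)))
}

#' Invert the encoding model
#'
#' Reconstructs channel responses from held-out sensor data by
#' least-squares inversion of the weights: `C2 = (W'W)^-1 W' B`.
#'
#' @param W weight matrix, sensors x channels, full column rank.
#' @param B sensor data, sensors x test trials.
#' @return channel responses, channels x test trials.
#' @export
invertModel <- function(W, B) {
  G <- crossprod(W)
  kappa <- suppressWarnings(kappa(G, exact = TRUE))
  if (!is.finite(kappa) || kappa > 1e10)
    stop("rank-deficient weight matrix (condition number ",
         format(kappa, digits = 3), ")")
  solve(G, crossprod(W, B))
}

#' Deterministic stratified cross-validation folds
#'
#' Assigns fold ids round-robin within strata defined by orientation x
#' condition, so every training fold contains all orientations (full-rank
#' channel design) and conditions in proportion. Deterministic: no RNG.
#'
#' @param design design table of the retained trials.
#' @param k number of folds for `"kfold"`.
#' @param scheme `"kfold"` or `"loo"` (leave-one-out).
#' @return integer vector of fold ids, one per trial.
#' @export
makeFolds <- function(design, k = 10L, scheme = c("kfold", "loo")) {
  scheme <- match.arg(scheme)
  n <- nrow(design)
  if (scheme == "loo") return(seq_len(n))
  strata <- interaction(design$orientation_second, design$condition,
                        drop = TRUE)
  fold <- integer(n)
  for (si in seq_along(levels(strata))) {
    idx <- which(as.integer(strata) == si)
    fold[idx] <- ((seq_along(idx) - 1L + si) %% k) + 1L
  }
  fold
}

# Window-averaged sensor features for every sliding-window position.
# Returns list(feats = [trials x sensors x positions], times = centres).
slidingFeatures <- function(epochs, windowMs, stepMs, timeRange = NULL) {
  rate <- epochs@sampleRate
  wlen <- max(1L, as.integer(round(windowMs / 1000 * rate)))
  step <- max(1L, as.integer(round(stepMs / 1000 * rate)))
  tp <- timePoints(epochs)
  nSamp <- length(tp)
  starts <- seq(1L, nSamp - wlen + 1L, by = step)
  centres <- tp[starts] + (wlen - 1) / (2 * rate)
  if (!is.null(timeRange)) {
    keep <- centres >= timeRange[1L] - 1e-9 & centres <= timeRange[2L] + 1e-9
    if (!any(keep)) stop("no window positions inside timeRange")
    starts <- starts[keep]; centres <- centres[keep]
  }
  d <- epochs@data
  feats <- array(0, dim = c(dim(d)[1L], dim(d)[2L], length(starts)))
  for (p in seq_along(starts)) {
    idx <- starts[p]:(starts[p] + wlen - 1L)
    feats[, , p] <- if (length(idx) == 1L) d[, , idx] else
      rowMeans(d[, , idx, drop = FALSE], dims = 2L)
  }
  list(feats = feats, times = centres)
}

retainedEpochs <- function(epochs) {
  keep <- !epochs@rejected
  if (!all(keep)) {
    epochs@data <- epochs@data[keep, , , drop = FALSE]
    epochs@design <- epochs@design[keep, , drop = FALSE]
    rownames(epochs@design) <- NULL
    epochs@rejected <- rep(FALSE, sum(keep))
  }
  epochs
}

#' Time-resolved cross-validated channel responses
#'
#' The core inverted-encoding loop: at every position of a sliding window
#' (16 ms wide, 4 ms steps by default), sensor features are the
#' within-window sample average; encoding weights are estimated on the
#' training folds ([fitWeights()]) and inverted on the held-out trials
#' ([invertModel()]) until every trial has a test response. All trial
#' types, including coloured-target trials, are used. Rejected trials are
#' excluded.
#'
#' @param epochs a preprocessed \linkS4class{EpochsArray}.
#' @param basis a \linkS4class{BasisSet}.
#' @param windowMs sliding window width, ms.
#' @param stepMs step between window positions, ms.
#' @param cvScheme `"kfold"` (default, 10 folds) or `"loo"`.
#' @param k number of folds for `"kfold"`.
#' @param timeRange optional numeric(2): restrict window centres to this
#'   interval (seconds, first-stimulus anchored).
#' @return an uncentered \linkS4class{ChannelResponseTensor}; the fold id
#'   used for each trial is recorded in its design column `cv_fold`.
#' @export
encodeTimecourse <- function(epochs, basis = makeBasis(), windowMs = 16,
                             stepMs = 4, cvScheme = c("kfold", "loo"),
                             k = 10L, timeRange = NULL) {
  cvScheme <- match.arg(cvScheme)
  epochs <- retainedEpochs(epochs)
  des <- epochs@design
  n <- nrow(des)
  Cfull <- buildDesignMatrix(des$orientation_second, basis)
  fold <- makeFolds(des, k = k, scheme = cvScheme)
  nCh <- nrow(Cfull)
  trainSizes <- vapply(unique(fold), function(f) sum(fold != f), integer(1))
  if (min(trainSizes) < nCh)
    stop("cv folds leave fewer training trials (", min(trainSizes),
         ") than channels (", nCh, ")")
  sw <- slidingFeatures(epochs, windowMs, stepMs, timeRange)
  P <- length(sw$times)
  resp <- array(NA_real_, dim = c(n, nCh, P))
  folds <- sort(unique(fold))
  for (p in seq_len(P)) {
    Fp <- t(sw$feats[, , p])                       # sensors x trials
    for (f in folds) {
      tr <- fold != f; te <- !tr
      W <- fitWeights(Fp[, tr, drop = FALSE], Cfull[, tr, drop = FALSE])
      # a window with (near-)zero sensor data gives rank-deficient weights;
      # the reconstructed response there is zero by convention
      resp[te, , p] <- tryCatch(t(invertModel(W, Fp[, te, drop = FALSE])),
                                error = function(e) 0)
    }
  }
  des$cv_fold <- fold
  new("ChannelResponseTensor", responses = resp, centered = FALSE,
      timeAxis = sw$times, offsets = basis@centers, design = des)
}

#' Center channel responses on the presented orientation
#'
#' Circularly shifts each trial's channel-response vector so the channel
#' tuned to the trial's presented (second-Gabor) orientation lands at
#' offset 0 degrees, the middle of the -80 ... +80 offset axis. Centering
#' permutes channels, so the across-channel sum is preserved.
#'
#' @param tensor an uncentered \linkS4class{ChannelResponseTensor} whose
#'   channels sit on the 9-orientation grid.
#' @return the centered \linkS4class{ChannelResponseTensor}.
#' @export
centerResponses <- function(tensor) {
  if (tensor@centered) stop("responses are already centered")
  nCh <- length(tensor@offsets)
  mid <- (nCh + 1L) %/% 2L
  step <- 180 / nCh
  oriIdx <- match(tensor@design$orientation_second %% 180, tensor@offsets)
  if (anyNA(oriIdx))
    stop("presented orientations must lie on the channel-centre grid")
  out <- tensor@responses
  for (i in seq_len(dim(out)[1L])) {
    chan <- ((oriIdx[i] + seq_len(nCh) - mid - 1L) %% nCh) + 1L
    out[i, , ] <- tensor@responses[i, chan, , drop = FALSE]
  }
  tensor@responses <- out
  tensor@centered <- TRUE
  tensor@offsets <- (seq_len(nCh) - mid) * step
  tensor
}

# Cosine-projection selectivity of a centered response curve: the first
# Fourier component over the 180-degree offset axis. Positive when the
# response peaks at offset 0.
selectivityWeights <- function(offsets) cos(offsets * pi / 90) * (2 / length(offsets))

#' Selectivity of centered responses over time
#'
#' Summarises a centered tensor as one selectivity value per time point:
#' the mean response curve projected onto a cosine over the offset axis
#' (its first Fourier component). This is the cheap selectivity metric used
#' by cross-temporal generalisation; Gaussian-fit amplitudes are the
#' refined alternative (see [selectivityTimecourse()]).
#'
#' @param tensor a centered \linkS4class{ChannelResponseTensor}.
#' @param trials optional trial subset (indices or logical).
#' @return numeric vector, one value per time point.
#' @export
responseSelectivity <- function(tensor, trials = NULL) {
  if (!tensor@centered) stop("tensor must be centered")
  r <- tensor@responses
  if (!is.null(trials)) r <- r[trials, , , drop = FALSE]
  curve <- colMeans(r)                     # channels x times
  drop(crossprod(curve, selectivityWeights(tensor@offsets)))
}

#' Cross-temporal generalisation of the encoder
#'
#' Trains encoding weights at one time point (on the training folds) and
#' applies them at every time point of the held-out trials, mapping how the
#' orientation-selective spatial pattern generalises across time. The
#' entry (t1, t2) is the selectivity (cosine projection of the centered
#' mean response) of weights trained at t1 tested at t2; the diagonal
#' equals the selectivity of the ordinary time course.
#'
#' @inheritParams encodeTimecourse
#' @param stepMs step between window positions (default 16 ms; the map is
#'   quadratic in the number of positions).
#' @return a \linkS4class{GeneralizationMap}.
#' @export
crossTemporalGeneralise <- function(epochs, basis = makeBasis(),
                                    windowMs = 16, stepMs = 16,
                                    cvScheme = c("kfold", "loo"), k = 10L,
                                    timeRange = NULL) {
  cvScheme <- match.arg(cvScheme)
  epochs <- retainedEpochs(epochs)
  des <- epochs@design
  n <- nrow(des)
  Cfull <- buildDesignMatrix(des$orientation_second, basis)
  fold <- makeFolds(des, k = k, scheme = cvScheme)
  sw <- slidingFeatures(epochs, windowMs, stepMs, timeRange)
  P <- length(sw$times)
  nCh <- nrow(Cfull)
  mid <- (nCh + 1L) %/% 2L
  oriIdx <- match(des$orientation_second %% 180, basis@centers)
  wsel <- selectivityWeights((seq_len(nCh) - mid) * (180 / nCh))
  folds <- sort(unique(fold))
  sel <- matrix(0, P, P)
  shiftIdx <- vapply(seq_len(n), function(i)
    ((oriIdx[i] + seq_len(nCh) - mid - 1L) %% nCh) + 1L, integer(nCh))
  for (p1 in seq_len(P)) {
    Fp1 <- t(sw$feats[, , p1])
    acc <- matrix(0, nCh, P)
    for (f in folds) {
      tr <- fold != f; te <- which(!tr)
      W <- fitWeights(Fp1[, tr, drop = FALSE], Cfull[, tr, drop = FALSE])
      Bte <- matrix(aperm(sw$feats[te, , , drop = FALSE], c(2L, 1L, 3L)),
                    nrow = dim(sw$feats)[2L])   # sensors x (nte*P)
      R <- tryCatch(invertModel(W, Bte),        # channels x (nte*P)
                    error = function(e) matrix(0, nCh, ncol(Bte)))
      R <- array(R, dim = c(nCh, length(te), P))
      for (j in seq_along(te))                  # center each test trial
        acc <- acc + R[shiftIdx[, te[j]], j, ]
    }
    sel[p1, ] <- crossprod(acc / n, wsel)
  }
  new("GeneralizationMap", selectivity = sel, trainTimes = sw$times,
      testTimes = sw$times)
}

#' Export a generalisation map as CSV
#'
#' Writes the train x test selectivity matrix with the time axes recorded
#' in `#`-prefixed header comments.
#'
#' @param map a \linkS4class{GeneralizationMap}.
#' @param path output file.
#' @export
writeGeneralizationMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# train_times_s: ", paste(map@trainTimes, collapse = ",")),
    paste0("# test_times_s: ", paste(map@testTimes, collapse = ","))), con)
  utils::write.table(map@selectivity, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
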