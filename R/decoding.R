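#' Diagonal-covariance naive Bayes classifier
#'
#' Gaussian class-conditional model with a diagonal covariance matrix:
#' class means per feature, with the per-feature variance pooled across
#' classes (`"diaglinear"`, diagonal LDA; the default) or estimated per
#' class (`"diagquadratic"`). Priors are uniform; prediction is the
#' maximum-posterior class, ties broken towards the lowest class index
#' (with a message). Zero-variance features are floored at
#' `varianceFloor` (with a message).
#'
#' @param Xtrain training features, trials x features.
#' @param labelsTrain factor (or coercible) of training labels; every class
#'   needs at least 2 training examples.
#' @param Xtest test features, trials x features.
#' @param type `"diaglinear"` or `"diagquadratic"`.
#' @param varianceFloor lower bound applied to variance estimates.
#' @return list: `labels` (predicted, same levels as training),
#'   `posterior` (trials x classes, rows sum to 1).
#' @export
nbFitPredict <- function(Xtrain, labelsTrain, Xtest,
                         type = c("diaglinear", "diagquadratic"),
                         varianceFloor = 1e-12) {
  type <- match.arg(type)
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  y <- factor(labelsTrain)
  classes <- levels(y)
  nc <- length(classes)
  counts <- table(y)
  if (any(counts < 2L))
    stop("every class needs >= 2 training examples; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  p <- ncol(Xtrain)
  mu <- matrix(0, nc, p)
  for (ci in seq_len(nc)) mu[ci, ] <- colMeans(Xtrain[y == classes[ci], ,
                                                      drop = FALSE])
  if (type == "diaglinear") {
    ssw <- numeric(p)
    for (ci in seq_len(nc)) {
      Z <- sweep(Xtrain[y == classes[ci], , drop = FALSE], 2L, mu[ci, ])
      ssw <- ssw + colSums(Z^2)
    }
    v <- ssw / (nrow(Xtrain) - nc)
    if (any(v < varianceFloor)) {
      message(sum(v < varianceFloor),
              " zero-variance feature(s) floored at ", varianceFloor)
      v <- pmax(v, varianceFloor)
    }
    V <- matrix(v, nc, p, byrow = TRUE)
  } else {
    V <- matrix(0, nc, p)
    for (ci in seq_len(nc)) {
      Z <- sweep(Xtrain[y == classes[ci], , drop = FALSE], 2L, mu[ci, ])
      V[ci, ] <- colSums(Z^2) / (sum(y == classes[ci]) - 1L)
    }
    if (any(V < varianceFloor)) {
      message(sum(V < varianceFloor),
              " zero-variance feature(s) floored at ", varianceFloor)
      V <- pmax(V, varianceFloor)
    }
  }
  logp <- matrix(0, nrow(Xtest), nc)
  for (ci in seq_len(nc)) {
    Z <- sweep(Xtest, 2L, mu[ci, ])
    logp[, ci] <- -0.5 * sum(log(2 * pi * V[ci, ])) -
      0.5 * rowSums(sweep(Z^2, 2L, V[ci, ], "/"))
  }
  m <- apply(logp, 1L, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  colnames(post) <- classes
  idx <- apply(post, 1L, which.max)      # first max = lowest class index
  nties <- sum(apply(post, 1L, function(r) sum(r == max(r)) > 1L))
  if (nties > 0L)
    message(nties, " tied posterior(s) broken towards the lowest class index")
  list(labels = factor(classes[idx], levels = classes), posterior = post)
}

#' Time-resolved backward decoding of orientation
#'
#' At every sliding-window position (the same window-averaged sensor
#' features as the encoder, so forward and backward analyses are
#' like-for-like), a diagonal naive Bayes classifier is trained on the
#' training folds and predicts the presented (second-Gabor) orientation of
#' the held-out trials. A trial is correct when the predicted orientation
#' equals the presented one; chance is 1/9. Training pools all conditions;
#' per-condition accuracy is computed from the pooled-classifier
#' predictions (train per condition by subsetting the epochs first).
#'
#' @inheritParams encodeTimecourse
#' @param type classifier variant, see [nbFitPredict()].
#' @return a list of class `DecodingResult`: `times`, `accuracy` (per time
#'   point, pooled over trials), `predictions` (trials x times factor
#'   matrix of predicted orientations), `design`, `nClasses`.
#' @export
decodeTimecourse <- function(epochs, windowMs = 16, stepMs = 4,
                             cvScheme = c("kfold", "loo"), k = 10L,
                             timeRange = NULL,
                             type = c("diaglinear", "diagquadratic")) {
  cvScheme <- match.arg(cvScheme); type <- match.arg(type)
  epochs <- retainedEpochs(epochs)
  des <- epochs@design
  n <- nrow(des)
  y <- factor(des$orientation_second, levels = ORIENTATION_GRID)
  fold <- makeFolds(des, k = k, scheme = cvScheme)
  sw <- slidingFeatures(epochs, windowMs, stepMs, timeRange)
  P <- length(sw$times)
  pred <- matrix(NA_character_, n, P)
  folds <- sort(unique(fold))
  for (p in seq_len(P)) {
    Fp <- sw$feats[, , p]
    for (f in folds) {
      tr <- fold != f; te <- !tr
      fit <- nbFitPredict(Fp[tr, , drop = FALSE], y[tr],
                          Fp[te, , drop = FALSE], type = type)
      pred[te, p] <- as.character(fit$labels)
    }
  }
  acc <- colMeans(pred == as.character(y))
  des$cv_fold <- fold
  structure(list(times = sw$times, accuracy = acc, predictions = pred,
                 design = des, nClasses = length(ORIENTATION_GRID)),
            class = "DecodingResult")
}

#' @export
print.DecodingResult <- function(x, ...) {
  cat(sprintf(
    "DecodingResult: %d trials x %d time points; accuracy %.3f .. %.3f (chance %.3f)\n",
    nrow(x$predictions), length(x$times), min(x$accuracy), max(x$accuracy),
    1 / x$nClasses))
  invisible(x)
}

#' Peak decoding accuracy in a post-stimulus window
#'
#' The maximum of the accuracy time course within a window anchored at
#' second-Gabor onset (600 ms wide by default), optionally per group
#' (accuracy recomputed from the held-out predictions of each group's
#' trials).
#'
#' @param result a `DecodingResult` from [decodeTimecourse()].
#' @param windowS window length in seconds after second-Gabor onset.
#' @param grouping `NULL` for all trials pooled, or a grouping as in
#'   [selectivityTimecourse()].
#' @return a `data.frame`: group, peak_accuracy, peak_time_s.
#' @export
peakAccuracy <- function(result, windowS = 0.6, grouping = NULL) {
  soa <- unique(result$design$onset_second_s)
  if (length(soa) != 1L) stop("non-unique second-stimulus onset in design")
  sel <- result$times >= soa - 1e-9 & result$times <= soa + windowS + 1e-9
  if (!any(sel)) stop("empty peak-accuracy window")
  truth <- as.character(result$design$orientation_second)
  g <- if (is.null(grouping)) rep("all", nrow(result$design))
       else designFactor(result$design, grouping)
  rows <- lapply(sort(unique(g)), function(lev) {
    tr <- g == lev
    acc <- colMeans(result$predictions[tr, sel, drop = FALSE] == truth[tr])
    i <- which.max(acc)
    data.frame(group = lev, peak_accuracy = acc[i],
               peak_time_s = result$times[sel][i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
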