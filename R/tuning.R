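# Gaussian kernel over a uniform time axis. `kernelMs` is the FWHM;
# sd = FWHM / (2 sqrt(2 log 2)), truncated at +/- 2 sd, reflected edges.
gaussianKernel <- function(kernelMs, dtS) {
  sdS <- (kernelMs / 1000) / (2 * sqrt(2 * log(2)))
  sdSamp <- sdS / dtS
  half <- ceiling(2 * sdSamp)
  if (half < 1L) return(NULL)
  kk <- exp(-(seq(-half, half))^2 / (2 * sdSamp^2))
  kk / sum(kk)
}

smoothVector <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  if (n < half + 2L) {            # too short to reflect; repeat the edges
    padl <- rep(x[1L], half); padr <- rep(x[n], half)
  } else {
    padl <- x[(half + 1L):2L]; padr <- x[(n - 1L):(n - half)]
  }
  stats::convolve(c(padl, x, padr), rev(kernel), type = "filter")
}

#' Temporal smoothing of channel responses
#'
#' Convolves every trial's channel time course with a normalised Gaussian
#' kernel. The `kernelMs` argument is the kernel's full width at half
#' maximum (16 ms by default); the kernel is truncated at two standard
#' deviations and edges are handled by reflection, so constants pass
#' through unchanged. A kernel narrower than one sample leaves the tensor
#' untouched (with a message).
#'
#' @param tensor a \linkS4class{ChannelResponseTensor} with a uniform time
#'   axis.
#' @param kernelMs Gaussian FWHM in milliseconds.
#' @return the smoothed \linkS4class{ChannelResponseTensor}.
#' @export
smoothTimecourse <- function(tensor, kernelMs = 16) {
  ta <- tensor@timeAxis
  if (length(ta) < 2L) return(tensor)
  dt <- diff(ta)
  if (diff(range(dt)) > 1e-9) stop("time axis must be uniform")
  kernel <- gaussianKernel(kernelMs, dt[1L])
  if (is.null(kernel) || length(kernel) < 3L) {
    message("smoothing kernel shorter than one sample; returning input")
    return(tensor)
  }
  r <- tensor@responses
  for (i in seq_len(dim(r)[1L]))
    for (ch in seq_len(dim(r)[2L]))
      r[i, ch, ] <- smoothVector(r[i, ch, ], kernel)
  tensor@responses <- r
  tensor
}

# Profiled least squares: for fixed (phi, sigma) the model
# A*exp(-(x-phi)^2/(2 sigma^2)) + C is linear in (A, C).
profiledGaussianRss <- function(phi, sigma, x, y) {
  g <- exp(-(x - phi)^2 / (2 * sigma^2))
  X <- cbind(g, 1)
  fit <- stats::lm.fit(X, y)
  list(A = fit$coefficients[1L], C = fit$coefficients[2L],
       rss = sum(fit$residuals^2))
}

#' Fit a Gaussian tuning function to a centered response curve
#'
#' Quantifies orientation selectivity by fitting
#' `A * exp(-(x - phi)^2 / (2 sigma^2)) + C` to the 9-point centered
#' channel response by nonlinear least squares. `A` is the amount of
#' orientation-selective activity, `phi` the centre (degrees), `sigma` the
#' width (degrees) and `C` a constant capturing non-selective baseline
#' shifts. The fit profiles out the linear parameters (A, C are solved in
#' closed form for each candidate phi, sigma), multi-starts from a
#' deterministic grid over (phi, sigma), and polishes the best start with
#' bounded quasi-Newton iterations. Bounds: `sigma` in [5, 90] degrees and
#' `phi` in [-20, 20] degrees — nine data points cannot constrain wider or
#' further-shifted Gaussians, and the bound stops a flat curve from being
#' explained by a huge-sigma Gaussian instead of A ~ 0.
#'
#' @param response numeric vector of channel responses (one per offset).
#' @param offsets offset axis in degrees (default -80 ... 80 by 20).
#' @param sigmaBounds,phiBounds parameter bounds, degrees.
#' @return a list of class `TuningFit`: `A`, `phi`, `sigma`, `C`, `rss`,
#'   `converged`.
#' @export
fitTuningCurve <- function(response, offsets = seq(-80, 80, by = 20),
                           sigmaBounds = c(5, 90), phiBounds = c(-20, 20)) {
  if (!all(is.finite(response))) stop("non-finite response values")
  if (length(response) != length(offsets))
    stop("response and offsets lengths differ")
  y <- as.numeric(response); x <- as.numeric(offsets)
  starts <- expand.grid(phi = c(phiBounds[1L], phiBounds[1L] / 2, 0,
                                phiBounds[2L] / 2, phiBounds[2L]),
                        sigma = c(10, 20, 30, 45, 60, 80))
  starts$sigma <- pmin(pmax(starts$sigma, sigmaBounds[1L]), sigmaBounds[2L])
  rssOf <- function(p) profiledGaussianRss(p[1L], p[2L], x, y)$rss
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$phi[i], starts$sigma[i])
    r <- rssOf(p0)
    if (is.null(best) || r < best$rss) best <- list(par = p0, rss = r)
  }
  opt <- tryCatch(
    stats::optim(best$par, rssOf, method = "L-BFGS-B",
                 lower = c(phiBounds[1L], sigmaBounds[1L]),
                 upper = c(phiBounds[2L], sigmaBounds[2L]),
                 control = list(factr = 1e4)),
    error = function(e) list(par = best$par, value = best$rss,
                             convergence = 1L))
  par <- if (opt$value <= best$rss) opt$par else best$par
  lin <- profiledGaussianRss(par[1L], par[2L], x, y)
  structure(list(A = unname(lin$A), phi = unname(par[1L]),
                 sigma = unname(par[2L]), C = unname(lin$C),
                 rss = lin$rss, converged = identical(opt$convergence, 0L)),
            class = "TuningFit")
}

#' @export
print.TuningFit <- function(x, ...) {
  cat(sprintf(
    "TuningFit: A=%.4g phi=%.3g deg sigma=%.3g deg C=%.4g (rss %.3g%s)\n",
    x$A, x$phi, x$sigma, x$C, x$rss,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

designFactor <- function(design, grouping) {
  if (grouping %in% names(design)) return(design[[grouping]])
  switch(grouping,
    expectation = sub("_.*$", "", design$condition),
    repetition  = sub("^.*_", "", design$condition),
    stop("unknown grouping '", grouping, "'"))
}

#' Time-resolved tuning fits per condition
#'
#' For each level of the grouping (the four conditions, or the expectation
#' / repetition margins), averages the centered responses over trials,
#' smooths the mean curve over time with the Gaussian kernel, and fits the
#' tuning Gaussian at every time point, yielding A(t), phi(t), sigma(t),
#' C(t).
#'
#' @param tensor a centered \linkS4class{ChannelResponseTensor}.
#' @param grouping `"condition"`, `"expectation"`, `"repetition"`, or any
#'   design column.
#' @param kernelMs temporal smoothing FWHM, ms ([smoothTimecourse]).
#' @param ... passed to [fitTuningCurve()].
#' @return a `data.frame`: group, time, A, phi, sigma, C, rss, converged.
#' @export
selectivityTimecourse <- function(tensor, grouping = "condition",
                                  kernelMs = 16, ...) {
  if (!tensor@centered) stop("tensor must be centered")
  g <- designFactor(tensor@design, grouping)
  groups <- sort(unique(g))
  out <- list()
  kernel <- if (length(tensor@timeAxis) >= 2L)
    gaussianKernel(kernelMs, diff(tensor@timeAxis)[1L]) else NULL
  for (lev in groups) {
    tr <- which(g == lev)
    if (length(tr) == 0L) stop("empty condition cell: ", lev)
    curve <- colMeans(tensor@responses[tr, , , drop = FALSE])  # ch x time
    if (!is.null(kernel) && length(kernel) >= 3L)
      for (ch in seq_len(nrow(curve)))
        curve[ch, ] <- smoothVector(curve[ch, ], kernel)
    fits <- lapply(seq_len(ncol(curve)), function(ti)
      fitTuningCurve(curve[, ti], tensor@offsets, ...))
    out[[lev]] <- data.frame(
      group = lev, time = tensor@timeAxis,
      A = vapply(fits, `[[`, numeric(1), "A"),
      phi = vapply(fits, `[[`, numeric(1), "phi"),
      sigma = vapply(fits, `[[`, numeric(1), "sigma"),
      C = vapply(fits, `[[`, numeric(1), "C"),
      rss = vapply(fits, `[[`, numeric(1), "rss"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Window-averaged tuning fits
#'
#' Averages the centered responses over a time window first (boosting
#' signal-to-noise), then over trials within each group, and fits one
#' tuning Gaussian per group. The typical use is one call per subject on
#' the early selectivity window, producing a table suitable for paired
#' tests across subjects.
#'
#' @param tensor a centered \linkS4class{ChannelResponseTensor}.
#' @param window numeric(2), seconds on the tensor's time axis.
#' @param grouping as in [selectivityTimecourse()].
#' @param ... passed to [fitTuningCurve()].
#' @return a `data.frame`: group, A, phi, sigma, C, rss, converged, n_trials.
#' @export
windowAverageFit <- function(tensor, window, grouping = "condition", ...) {
  if (!tensor@centered) stop("tensor must be centered")
  ta <- tensor@timeAxis
  idx <- which(ta >= window[1L] - 1e-9 & ta <= window[2L] + 1e-9)
  if (length(idx) == 0L)
    stop("window [", window[1L], ", ", window[2L],
         "] s is outside the tensor time axis")
  g <- designFactor(tensor@design, grouping)
  groups <- sort(unique(g))
  rows <- lapply(groups, function(lev) {
    tr <- which(g == lev)
    if (length(tr) == 0L) stop("empty condition cell: ", lev)
    curve <- apply(tensor@responses[tr, , idx, drop = FALSE], 2L, mean)
    fit <- fitTuningCurve(curve, tensor@offsets, ...)
    data.frame(group = lev, A = fit$A, phi = fit$phi, sigma = fit$sigma,
               C = fit$C, rss = fit$rss, converged = fit$converged,
               n_trials = length(tr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
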