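# One-sample t statistics per column of a subjects x points matrix.
groupTStat <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

#' Sign-flip permutation null for a group statistic
#'
#' Builds the null distribution of the one-sample group t statistic by
#' randomly flipping the sign of each subject's entire series with equal
#' probability — the exchangeability argument for difference scores under
#' the null of no condition difference. Deterministic given the seed.
#'
#' @param subjectData subjects x points matrix of per-subject difference
#'   scores (tested against 0).
#' @param nPerm number of permutations (a warning below 100).
#' @param seed integer seed.
#' @return `nPerm` x points matrix of null t statistics.
#' @export
signFlipNull <- function(subjectData, nPerm = 1000L, seed = 1L) {
  X <- as.matrix(subjectData)
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 subjects")
  if (nPerm < 100L) warning("fewer than 100 permutations; p-values are coarse")
  withSeed(seed, {
    FL <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    M <- FL %*% X / n
    SS <- matrix(colSums(X^2), nPerm, ncol(X), byrow = TRUE)
    V <- (SS - n * M^2) / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    Tm
  })
}

# Contiguous supra-threshold runs of a 1-d statistic series.
findClusters1d <- function(stat, tcrit, tail) {
  supra <- switch(tail,
    two_sided = abs(stat) > tcrit,
    greater   = stat > tcrit,
    less      = stat < -tcrit)
  if (!any(supra)) return(list())
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values))
    out[[length(out) + 1L]] <- starts[i]:ends[i]
  out
}

# 4-connected components of a logical matrix (BFS flood fill).
findClusters2d <- function(supra) {
  nr <- nrow(supra); nc <- ncol(supra)
  lab <- matrix(0L, nr, nc)
  out <- list()
  for (start in which(supra)) {
    if (lab[start]) next
    queue <- start
    lab[start] <- 1L
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      members <- c(members, cur)
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                   if (j > 1L) cur - nr, if (j < nc) cur + nr)) {
        if (supra[nb] && lab[nb] == 0L) {
          lab[nb] <- 1L
          queue <- c(queue, nb)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

maxClusterMass <- function(stat, tcrit, tail, dims = NULL) {
  if (is.null(dims)) {
    cl <- findClusters1d(stat, tcrit, tail)
  } else {
    sm <- matrix(stat, dims[1L], dims[2L])
    supra <- switch(tail,
      two_sided = abs(sm) > tcrit,
      greater   = sm > tcrit,
      less      = sm < -tcrit)
    cl <- findClusters2d(supra)
  }
  if (!length(cl)) return(0)
  max(vapply(cl, function(ix) abs(sum(stat[ix])), numeric(1)))
}

#' Cluster-mass permutation test
#'
#' Nonparametric correction for multiple comparisons over a time series
#' (1-d) or a train x test time grid (2-d, 4-connected): clusters are
#' formed from contiguous points whose group t statistic exceeds the
#' parametric two-sided threshold at `thresholdP` (df = subjects - 1),
#' cluster mass is the summed t within a cluster, and the corrected
#' p-value is the fraction of sign-flip permutations whose maximum
#' absolute cluster mass reaches the observed one, with the +1 correction
#' so p is never exactly zero.
#'
#' @param subjectData subjects x points matrix of difference scores, or a
#'   subjects x train x test 3-d array for a 2-d map.
#' @param nPerm number of sign-flip permutations.
#' @param thresholdP pointwise cluster-forming alpha (two-sided t).
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @param seed integer seed for the permutation draws.
#' @return a list of class `ClusterTestResult`: `observed` (t series or
#'   matrix), `clusters` (each with `indices`, `mass`, `p_value`),
#'   `tcrit`, `nPerm`, `tail`. No supra-threshold point yields an empty
#'   cluster list.
#' @export
clusterTest <- function(subjectData, nPerm = 1000L, thresholdP = 0.05,
                        tail = c("two_sided", "greater", "less"),
                        seed = 1L) {
  tail <- match.arg(tail)
  dims <- NULL
  if (is.array(subjectData) && length(dim(subjectData)) == 3L) {
    dims <- dim(subjectData)[2:3]
    subjectData <- matrix(subjectData, nrow = dim(subjectData)[1L])
  }
  X <- as.matrix(subjectData)
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 subjects")
  df <- n - 1L
  tcrit <- stats::qt(1 - thresholdP / 2, df)
  obs <- groupTStat(X)
  if (is.null(dims)) {
    clIdx <- findClusters1d(obs, tcrit, tail)
  } else {
    om <- matrix(obs, dims[1L], dims[2L])
    supra <- switch(tail,
      two_sided = abs(om) > tcrit,
      greater   = om > tcrit,
      less      = om < -tcrit)
    clIdx <- findClusters2d(supra)
  }
  Tnull <- signFlipNull(X, nPerm = nPerm, seed = seed)
  nullMax <- vapply(seq_len(nPerm), function(p)
    maxClusterMass(Tnull[p, ], tcrit, tail, dims), numeric(1))
  clusters <- lapply(clIdx, function(ix) {
    mass <- sum(obs[ix])
    # tolerance so the identity flip pattern (which reproduces the observed
    # statistic up to arithmetic roundoff) always counts against itself
    tol <- 1e-8 * max(1, abs(mass))
    list(indices = ix, mass = mass,
         p_value = (1 + sum(nullMax >= abs(mass) - tol)) / (nPerm + 1))
  })
  observed <- if (is.null(dims)) obs else matrix(obs, dims[1L], dims[2L])
  structure(list(observed = observed, clusters = clusters, tcrit = tcrit,
                 nPerm = nPerm, tail = tail),
            class = "ClusterTestResult")
}

#' @export
print.ClusterTestResult <- function(x, ...) {
  cat(sprintf("ClusterTestResult: %d cluster(s), |t| > %.3f, %d permutations\n",
              length(x$clusters), x$tcrit, x$nPerm))
  for (cl in x$clusters)
    cat(sprintf("  size %d, mass %.2f, p = %.4g\n",
                length(cl$indices), cl$mass, cl$p_value))
  invisible(x)
}

#' P1 / N1 peak amplitudes and latencies
#'
#' Classic ERP component measures on (bandpass-filtered) per-subject ERPs:
#' the P1 is the largest positivity 80-110 ms and the N1 the largest
#' negativity 90-130 ms after second-stimulus onset. Ties take the
#' earliest latency (with a message).
#'
#' @param erp subjects x samples matrix of ERP traces, microvolts.
#' @param time time axis in seconds, anchored at first-stimulus onset.
#' @param soa second-stimulus onset in seconds (component windows are
#'   relative to it).
#' @param p1Window,n1Window component windows in seconds post second
#'   stimulus.
#' @return a `data.frame` per subject: p1_amplitude, p1_latency_ms,
#'   n1_amplitude, n1_latency_ms (latencies relative to second-stimulus
#'   onset).
#' @export
erpPeakComponents <- function(erp, time, soa = 0.6,
                              p1Window = c(0.080, 0.110),
                              n1Window = c(0.090, 0.130)) {
  erp <- as.matrix(erp)
  if (ncol(erp) != length(time)) stop("erp columns must match time axis")
  winIdx <- function(w) {
    ix <- which(time >= soa + w[1L] - 1e-9 & time <= soa + w[2L] + 1e-9)
    if (!length(ix)) stop("component window [", w[1L], ", ", w[2L],
                          "] s outside the epoch")
    ix
  }
  p1Idx <- winIdx(p1Window); n1Idx <- winIdx(n1Window)
  pick <- function(v, ix, what) {
    vals <- if (what == "max") v[ix] else -v[ix]
    best <- which(vals == max(vals))
    if (length(best) > 1L) message("tied ", what, " peaks; earliest kept")
    i <- ix[best[1L]]
    c(v[i], (time[i] - soa) * 1000)
  }
  out <- t(vapply(seq_len(nrow(erp)), function(s) {
    p1 <- pick(erp[s, ], p1Idx, "max")
    n1 <- pick(erp[s, ], n1Idx, "min")
    c(p1, n1)
  }, numeric(4)))
  data.frame(subject = seq_len(nrow(erp)),
             p1_amplitude = out[, 1L], p1_latency_ms = out[, 2L],
             n1_amplitude = out[, 3L], n1_latency_ms = out[, 4L])
}

#' Paired-samples t-test
#'
#' Classical two-sided paired t; thin wrapper around [stats::t.test()]
#' returning the scalar results used by the pipeline report.
#'
#' @param x,y equal-length paired samples.
#' @return list: `t`, `df`, `p`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("need >= 2 pairs")
  if (stats::sd(x - y) == 0) {
    if (all(x == y))                       # identical samples: no effect
      return(list(t = 0, df = length(x) - 1L, p = 1))
    stop("zero variance of paired differences; t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
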