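# Small in-code fixtures shared across tests.

# compact session: 2 blocks of 45 trials (36/9 contingency split, 5/1 per
# orientation within cells)
smallDesign <- function(seed = 7, nBlocks = 2, trialsPerBlock = 45) {
  generateSessionDesign(nBlocks, trialsPerBlock, seed = seed)
}

# noiseless simulation around the second stimulus only (keeps arrays small)
noiselessConfig <- function(...) {
  args <- list(noiseSdUV = 0, pinkNoiseSdUV = 0, intersubjectGainSd = 0,
               epochWindow = c(0.4, 1.1), seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(SimulationConfig, args)
}

# tiny epochs with hand-set data: trials x sensors x samples
epochsFromArray <- function(dat, rate = 256, t0 = 0, soa = 0.6,
                            design = NULL) {
  n <- dim(dat)[1L]
  if (is.null(design)) {
    design <- data.frame(
      session_id = 1L, block_id = 1L, block_type = "repeating",
      trial_type = "repeat", condition = "expected_repeat",
      orientation_first = rep(ORIENTATION_GRID, length.out = n),
      orientation_second = rep(ORIENTATION_GRID, length.out = n),
      is_target = FALSE, onset_second_s = soa)
  }
  new("EpochsArray", data = dat, sampleRate = rate, t0 = t0,
      channelLabels = sprintf("S%02d", seq_len(dim(dat)[2L])),
      design = design, rejected = rep(FALSE, n))
}

# independent dense pseudoinverse oracle (SVD), used against invertModel
pinvOracle <- function(W, tol = 1e-10) {
  s <- svd(W)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# brute-force 4-D grid-search oracle for the Gaussian tuning fit
gridSearchOracle <- function(y, x = seq(-80, 80, by = 20)) {
  best <- Inf
  for (A in seq(-2, 2, by = 0.1))
    for (phi in seq(-20, 20, by = 5))
      for (sg in seq(5, 90, by = 5))
        for (C in seq(-1, 1, by = 0.1)) {
          rss <- sum((y - (A * exp(-(x - phi)^2 / (2 * sg^2)) + C))^2)
          if (rss < best) best <- rss
        }
  best
}

# exhaustive diagonal-Gaussian Bayes-rule oracle, coded independently of
# nbFitPredict
nbOracle <- function(Xtr, y, Xte) {
  y <- factor(y)
  cls <- levels(y)
  p <- ncol(Xtr)
  mu <- sapply(cls, function(cl) colMeans(Xtr[y == cl, , drop = FALSE]))
  pooled <- numeric(p)
  for (cl in cls) {
    Z <- Xtr[y == cl, , drop = FALSE]
    pooled <- pooled + colSums(sweep(Z, 2, colMeans(Z))^2)
  }
  v <- pooled / (nrow(Xtr) - length(cls))
  lik <- sapply(cls, function(cl) {
    apply(Xte, 1, function(x) prod(dnorm(x, mu[, cl], sqrt(v))))
  })
  lik <- matrix(lik, nrow = nrow(Xte))
  lik / rowSums(lik)
}

# reduced-scale recovery run: simulate a cohort, encode around the second
# stimulus, fit per-subject amplitude/width time courses by expectation,
# and cluster-test the contrasts (amplitude directional, as the injected
# direction is known; width same machinery, expected null).
leanRecoveryRun <- function(seed, gains = NULL, nSubjects = 5, nBlocks = 6,
                            nPerm = 1000) {
  simArgs <- list(nSubjects = nSubjects, seed = seed,
                  epochWindow = c(0.4, 1.1))
  if (!is.null(gains)) simArgs$gains <- gains
  cfg <- do.call(SimulationConfig, simArgs)
  cohort <- simulateCohort(cfg, nBlocks, 135)
  perSub <- lapply(cohort, function(s) {
    ep <- rejectThreshold(baselineCorrect(rereferenceCommonAverage(
      s$epochs)), 100)
    ten <- centerResponses(encodeTimecourse(ep, stepMs = 12,
                                            timeRange = c(0.58, 0.95)))
    selectivityTimecourse(ten, "expectation")
  })
  contrast <- function(param) t(sapply(perSub, function(f) {
    u <- f[f$group == "unexpected", ]
    e <- f[f$group == "expected", ]
    u[[param]][order(u$time)] - e[[param]][order(e$time)]
  }))
  sig <- function(ct) length(ct$clusters) > 0 &&
    any(sapply(ct$clusters, `[[`, "p_value") < 0.05)
  c(amp = sig(clusterTest(contrast("A"), nPerm, tail = "greater",
                          seed = seed + 7)),
    sigma = sig(clusterTest(contrast("sigma"), nPerm, tail = "greater",
                            seed = seed + 8)))
}
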