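test_that("sign-flip null behaves under symmetry, determinism and degeneracy", {
  X <- matrix(rnorm(8 * 30), 8, 30)
  n1 <- signFlipNull(X, nPerm = 500, seed = 4)
  n2 <- signFlipNull(X, nPerm = 500, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, signFlipNull(X, nPerm = 500, seed = 5)))
  # symmetry: the null t distribution is centred on zero
  expect_lt(abs(mean(n1)), 0.05)
  # all-zero data: null and observed statistics all zero
  Z <- matrix(0, 6, 10)
  expect_true(all(signFlipNull(Z, nPerm = 200, seed = 1) == 0))
  expect_warning(signFlipNull(X, nPerm = 50, seed = 1), "100")
})

test_that("cluster test finds an injected window and respects edge cases", {
  set.seed(2)
  n <- 12; T <- 60
  X <- matrix(rnorm(n * T, sd = 1), n, T)
  X[, 20:35] <- X[, 20:35] + 1.5
  ct <- clusterTest(X, nPerm = 500, seed = 3)
  expect_gt(length(ct$clusters), 0)
  big <- ct$clusters[[which.max(sapply(ct$clusters,
                                       function(cl) abs(cl$mass)))]]
  expect_lt(big$p_value, 0.05)
  covered <- mean(20:35 %in% big$indices)
  expect_gte(covered, 0.8)
  # p-values live in [1/(nPerm+1), 1]
  ps <- sapply(ct$clusters, function(cl) cl$p_value)
  expect_true(all(ps >= 1 / 501 & ps <= 1))

  # no supra-threshold points: empty cluster list is a valid result
  # (alternating +/- pattern has exactly zero group mean, so t = 0)
  calm <- matrix(rep(c(0.01, -0.01), length.out = n), n, T)
  expect_length(clusterTest(calm, nPerm = 200, seed = 1)$clusters, 0)

  # single supra-threshold point: cluster of size 1 with mass = its t
  one <- matrix(rep(c(0.01, -0.01), length.out = n), n, T)   # t = 0 cols
  one[, 30] <- 5 + rep(c(0.01, -0.01), length.out = n)       # t >> 0
  ct1 <- clusterTest(one, nPerm = 200, seed = 1)
  expect_length(ct1$clusters, 1)
  expect_identical(ct1$clusters[[1]]$indices, 30L)
  expect_equal(ct1$clusters[[1]]$mass, ct1$observed[30], tolerance = 1e-12)
})

test_that("2-d cluster test uses 4-connectivity on the grid", {
  n <- 10
  # zero-t background (alternating signs), plus a 3x3 block and two
  # diagonally adjacent points that 4-connectivity must keep separate
  arr <- array(rep(c(0.01, -0.01), length.out = n), dim = c(n, 8, 8))
  arr[, 2:4, 2:4] <- arr[, 2:4, 2:4] + 3
  arr[, 7, 7] <- arr[, 7, 7] + 4
  arr[, 8, 8] <- arr[, 8, 8] + 4
  ct <- clusterTest(arr, nPerm = 300, seed = 2)
  sizes <- sort(sapply(ct$clusters, function(cl) length(cl$indices)))
  expect_length(ct$clusters, 3)               # block + two diagonal singles
  expect_identical(sizes, c(1L, 1L, 9L))
})

test_that("sign-flip null quantiles are uniform under the null hypothesis", {
  # exchangeability: the observed statistic's null quantile ~ U(0,1)
  qs <- withSeed(17, replicate(200, {
    X <- matrix(rnorm(8 * 5), 8, 5)
    obs <- sum(colMeans(X))
    FL <- matrix(sample(c(-1, 1), 200 * 8, replace = TRUE), 200, 8)
    null <- (FL %*% X) %*% rep(1, 5) / 8
    mean(null <= obs)
  }))
  ks <- suppressWarnings(ks.test(qs, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("ERP component peaks are located analytically", {
  rate <- 256
  time <- seq(-0.5, 1.25 - 1 / rate, by = 1 / rate)
  bump <- function(amp, latS) amp * exp(-(time - 0.6 - latS)^2 / (2 * 0.01^2))
  # single positive bump at 95 ms: P1 there; N1 at a window edge
  erp <- rbind(bump(2, 0.095), bump(4, 0.095))
  comp <- erpPeakComponents(erp, time, soa = 0.6)
  expect_equal(comp$p1_latency_ms, c(95, 95), tolerance = 4)
  expect_equal(comp$p1_amplitude, c(2, 4), tolerance = 0.05)
  # linearity: amplitude-scaled bump scales the P1 difference
  expect_equal(comp$p1_amplitude[2] / comp$p1_amplitude[1], 2,
               tolerance = 0.01)
  # N1 is the window minimum of a positive trace: at an edge, small value
  expect_true(all(comp$n1_amplitude >= 0))
  expect_true(all(comp$n1_latency_ms >= 90 - 4 & comp$n1_latency_ms <= 130 + 4))
  # tie rule: flat trace -> earliest latency, message emitted
  expect_message(
    tie <- erpPeakComponents(matrix(1, 1, length(time)), time, soa = 0.6),
    "tied")
  expect_equal(tie$p1_latency_ms, 80, tolerance = 4)
  expect_error(erpPeakComponents(erp, time, soa = 2), "outside")
})

test_that("paired t matches the hand-computed textbook value", {
  res <- pairedT(c(1, 2, 3), c(2, 4, 6))
  # diffs -1, -2, -3: mean -2, sd 1, t = -2 / (1/sqrt(3))
  expect_equal(res$t, -2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t, -3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  same <- pairedT(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(pairedT(c(1, 5), c(2, 7))$df, 1)
  expect_error(pairedT(c(1, 2), c(2, 3)), "zero variance")
})
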