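test_that("common-average re-referencing zeroes the sensor mean and is idempotent", {
  dat <- array(rnorm(4 * 6 * 10), dim = c(4, 6, 10))
  ep <- epochsFromArray(dat)
  out <- rereferenceCommonAverage(ep)
  means <- apply(epochData(out), c(1, 3), mean)
  expect_true(all(abs(means) < 1e-12))
  again <- rereferenceCommonAverage(out)
  expect_equal(epochData(again), epochData(out), tolerance = 1e-14)

  # 2-sensor worked example: (3, -1) -> (2, -2)
  d2 <- array(c(3, -1), dim = c(1, 2, 1))
  out2 <- rereferenceCommonAverage(epochsFromArray(d2))
  expect_equal(drop(epochData(out2)), c(2, -2))

  expect_error(rereferenceCommonAverage(
    epochsFromArray(array(1, dim = c(1, 1, 4)))), "2 sensors")
})

test_that("band-pass response: passband ~1, DC and stopband strongly attenuated", {
  rate <- 256
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  mk <- function(x) epochsFromArray(array(rep(x, 2), dim = c(1, 2, length(x))),
                                    rate = rate)
  ampRatio <- function(freqHz) {
    x <- sin(2 * pi * freqHz * t)
    y <- epochData(filterEpochs(mk(x), 2, 40))[1, 1, ]
    core <- seq(rate, length(t) - rate)      # avoid edge transients
    max(abs(y[core])) / max(abs(x[core]))
  }
  expect_gt(ampRatio(10), 0.95)
  expect_lt(ampRatio(10), 1.05)
  expect_lt(ampRatio(100), 0.1)
  dc <- epochData(filterEpochs(mk(rep(5, length(t))), 2, 40))[1, 1, ]
  expect_lt(abs(mean(dc)), 0.05)             # residual < 1% of the offset
  expect_error(filterEpochs(mk(sin(t)), 2, 200), "Nyquist")
  expect_error(filterEpochs(mk(sin(t)), 130), "Nyquist")
})

test_that("baseline correction zeroes the anchored window and sees anchor shifts", {
  rate <- 256
  nS <- as.integer(rate * 1.75)
  # constant trial: identically zero after correction
  cst <- epochsFromArray(array(3.7, dim = c(2, 3, nS)), rate = rate, t0 = -0.5)
  expect_true(all(epochData(baselineCorrect(cst)) == 0))

  # random trials: baseline-window mean is 0 for every trial and sensor
  dat <- array(rnorm(2 * 3 * nS), dim = c(2, 3, nS))
  ep <- epochsFromArray(dat, rate = rate, t0 = -0.5)
  out <- baselineCorrect(ep, c(-0.1, 0), "second_gabor")
  tp <- timePoints(out)
  idx <- which(tp >= 0.5 - 1e-9 & tp <= 0.6 + 1e-9)
  expect_true(all(abs(apply(epochData(out)[, , idx], c(1, 2), mean)) < 1e-12))

  # linear ramp: first- vs second-anchored outputs differ by slope * SOA
  slope <- 2
  ramp <- array(rep(slope * tp, each = 6), dim = c(2, 3, nS))
  epr <- epochsFromArray(ramp, rate = rate, t0 = -0.5)
  d1 <- epochData(baselineCorrect(epr, c(-0.1, 0), "first_gabor"))
  d2 <- epochData(baselineCorrect(epr, c(-0.1, 0), "second_gabor"))
  # offset equals the slope times the (sampled) 600 ms anchor shift
  expect_equal(unique(round(c(d1 - d2), 9)), slope * 0.6, tolerance = 0.01)

  expect_error(baselineCorrect(ep, c(-2, -1.9)), "window")
})

test_that("threshold rejection counts exactly and never alters data", {
  dat <- array(rnorm(10 * 3 * 20, sd = 5), dim = c(10, 3, 20))
  hot <- c(2, 5, 9)
  dat[cbind(hot, 1, 4)] <- c(101, -150, 120)
  ep <- epochsFromArray(dat)
  out <- rejectThreshold(ep, 100)
  expect_identical(which(rejectedTrials(out)), as.integer(hot))
  expect_identical(epochData(out), dat)
  # boundary: |v| = 101 at threshold 100 rejected; all within +/-50 -> none
  calm <- epochsFromArray(array(runif(5 * 2 * 8, -50, 50), dim = c(5, 2, 8)))
  expect_equal(sum(rejectedTrials(rejectThreshold(calm, 100))), 0)
})

test_that("condition ERPs are trial-then-sensor means with exclusions honoured", {
  nS <- 16
  des <- data.frame(
    session_id = 1L, block_id = 1L, block_type = "repeating",
    trial_type = c("repeat", "repeat", "alternate", "alternate"),
    condition = c("expected_repeat", "expected_repeat",
                  "unexpected_alternate", "unexpected_alternate"),
    orientation_first = 0, orientation_second = c(0, 0, 20, 20),
    is_target = c(FALSE, TRUE, FALSE, FALSE), onset_second_s = 0.6)
  des$orientation_first <- c(0, 0, 40, 40)
  dat <- array(0, dim = c(4, 2, nS))
  dat[1, , ] <- 1; dat[2, , ] <- 100; dat[3, , ] <- -1; dat[4, , ] <- -3
  ep <- epochsFromArray(dat, design = des)
  res <- conditionERP(ep, "condition")
  # target trial excluded: expected_repeat ERP is trial 1 alone
  expect_equal(unique(res$erp["expected_repeat", ]), 1)
  expect_equal(unique(res$erp["unexpected_alternate", ]), -2)
  expect_equal(unname(res$n), c(1L, 2L))
  resAll <- conditionERP(ep, "condition", excludeTargets = FALSE)
  expect_equal(unique(resAll$erp["expected_repeat", ]), 50.5)
  expect_error(conditionERP(ep, "nope"), "grouping")
  expect_error(conditionERP(ep, "condition", sensors = "S99"), "sensor")
})

test_that("re-referencing and baseline correction commute", {
  rate <- 256
  nS <- as.integer(rate * 1.75)
  dat <- array(rnorm(3 * 4 * nS), dim = c(3, 4, nS))
  ep <- epochsFromArray(dat, rate = rate, t0 = -0.5)
  ab <- baselineCorrect(rereferenceCommonAverage(ep))
  ba <- rereferenceCommonAverage(baselineCorrect(ep))
  expect_equal(epochData(ab), epochData(ba), tolerance = 1e-12)
})
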