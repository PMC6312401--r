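test_that("well-separated classes are classified perfectly", {
  Xtr <- matrix(c(rep(0, 10), rep(10, 10)), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  Xte <- matrix(c(-1, 0.5, 9, 11), ncol = 1)
  fit <- nbFitPredict(Xtr, y, Xte)
  expect_identical(as.character(fit$labels), c("a", "a", "b", "b"))
})

test_that("posteriors equal the exhaustive Bayes-rule oracle and sum to 1", {
  set.seed(8)
  for (rep in 1:5) {
    Xtr <- matrix(rnorm(30 * 3, mean = rep(c(0, 1), each = 45)), 30, 3)
    y <- rep(c("u", "v"), each = 15)
    Xte <- matrix(rnorm(8 * 3), 8, 3)
    fit <- nbFitPredict(Xtr, y, Xte)
    expect_equal(unname(fit$posterior), unname(nbOracle(Xtr, y, Xte)),
                 tolerance = 1e-10)
    expect_equal(rowSums(fit$posterior), rep(1, 8), tolerance = 1e-10)
  }
})

test_that("label shuffling yields chance-level 9-class accuracy", {
  des <- smallDesign(nBlocks = 4, trialsPerBlock = 45)
  cfg <- SimulationConfig(
    gains = c(expected_repeat = 0, unexpected_repeat = 0,
              expected_alternate = 0, unexpected_alternate = 0),
    noiseSdUV = 1, pinkNoiseSdUV = 0, epochWindow = c(0.55, 0.75),
    seed = 21)
  ep <- simulateEpochs(des, cfg)$epochs
  dec <- decodeTimecourse(ep, stepMs = 32, timeRange = c(0.6, 0.72))
  accs <- dec$accuracy
  n <- nrow(dec$predictions)
  se <- sqrt((1 / 9) * (8 / 9) / n)
  expect_true(all(abs(accs - 1 / 9) < 4 * se))
  expect_lt(abs(mean(accs) - 1 / 9), 3 * se)
})

test_that("strong noiseless signal decodes near ceiling inside its window only", {
  des <- smallDesign()
  cfg <- noiselessConfig(noiseSdUV = 0.05)  # tiny noise so variances exist
  ep <- simulateEpochs(des, cfg)$epochs
  dec <- decodeTimecourse(ep, stepMs = 32, timeRange = c(0.45, 1.0))
  inWin <- dec$times > 0.73 & dec$times < 0.84
  before <- dec$times < 0.62
  expect_true(all(dec$accuracy[inWin] > 0.95))
  expect_true(all(abs(dec$accuracy[before] - 1 / 9) < 0.1))
})

test_that("higher condition gain gives higher per-condition peak accuracy", {
  des <- smallDesign(nBlocks = 4, trialsPerBlock = 45)
  cfg <- SimulationConfig(noiseSdUV = 1.5, pinkNoiseSdUV = 1,
                          epochWindow = c(0.45, 1.25), seed = 31)
  ep <- simulateEpochs(des, cfg)$epochs
  dec <- decodeTimecourse(ep, stepMs = 16, timeRange = c(0.6, 1.2))
  peaks <- peakAccuracy(dec, 0.6, "expectation")
  pu <- peaks$peak_accuracy[peaks$group == "unexpected"]
  pe <- peaks$peak_accuracy[peaks$group == "expected"]
  expect_gt(pu, 1 / 9)
  expect_gt(pe, 1 / 9)
  expect_gt(pu, pe - 0.05)   # ordinal claim at one-seed resolution
})

test_that("peak accuracy takes the window maximum", {
  des <- smallDesign()[1:20, ]
  times <- seq(0.6, 1.2, by = 0.02)
  mkResult <- function(acc) {
    pred <- matrix("0", 20, length(times))
    structure(list(times = times, accuracy = acc,
                   predictions = pred, design = des, nClasses = 9),
              class = "DecodingResult")
  }
  # build predictions so per-time accuracy equals a target profile
  target <- function(prof) {
    truth <- as.character(des$orientation_second)
    pred <- matrix("", 20, length(times))
    for (j in seq_along(times)) {
      nOK <- round(prof[j] * 20)
      pred[, j] <- ifelse(seq_len(20) <= nOK, truth, "badlabel")
    }
    r <- mkResult(colMeans(pred == truth))
    r$predictions <- pred
    r
  }
  ramp <- target(seq(0.05, 0.95, length.out = length(times)))
  pk <- peakAccuracy(ramp, 0.6)
  expect_equal(pk$peak_time_s, times[length(times)])
  flat <- target(rep(0.4, length(times)))
  expect_equal(peakAccuracy(flat, 0.6)$peak_accuracy, 0.4)
  bumps <- rep(0.1, length(times))
  bumps[5] <- 0.4; bumps[20] <- 0.6
  expect_equal(peakAccuracy(target(bumps), 0.6)$peak_accuracy, 0.6)
})

test_that("single-test-trial folds give 0/1 accuracies with a well-defined mean", {
  full <- smallDesign()
  idx <- unlist(lapply(split(seq_len(nrow(full)), full$orientation_second),
                       head, 3))               # 27 trials, 3 per class
  des <- full[sort(idx), ]
  cfg <- noiselessConfig(noiseSdUV = 0.2)
  ep <- simulateEpochs(des, cfg)$epochs
  dec <- decodeTimecourse(ep, stepMs = 32, timeRange = c(0.75, 0.8),
                          cvScheme = "loo")
  correct <- dec$predictions == as.character(des$orientation_second)
  expect_true(all(correct %in% c(TRUE, FALSE)))
  expect_true(all(dec$accuracy >= 0 & dec$accuracy <= 1))
})

test_that("degenerate training inputs are handled as specified", {
  expect_error(nbFitPredict(matrix(1:3, 3, 1), c("a", "a", "b"),
                            matrix(1, 1, 1)), ">= 2")
  # zero-variance feature floored with a message
  Xtr <- cbind(c(rep(0, 5), rep(1, 5)), 1)
  expect_message(nbFitPredict(Xtr, rep(c("a", "b"), each = 5),
                              matrix(c(0.2, 1), 1, 2)), "floored")
})
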