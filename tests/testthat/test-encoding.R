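test_that("weight estimation matches the normal-equations oracle and recovers noiseless truth", {
  set.seed(42)
  # small instance: independently coded normal equations per sensor row
  C <- matrix(runif(2 * 3), 2, 3)
  B <- matrix(rnorm(2 * 3), 2, 3)
  W <- fitWeights(B, C)
  oracle <- t(apply(B, 1, function(b)
    solve(C %*% t(C)) %*% (C %*% b)))
  expect_equal(W, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # noiseless identifiability: B = W0 C recovers W0 to 1e-8
  b9 <- makeBasis()
  Cg <- buildDesignMatrix(rep(seq(0, 160, by = 20), 3), b9)
  W0 <- matrix(rnorm(64 * 9), 64, 9)
  expect_lt(max(abs(fitWeights(W0 %*% Cg, Cg) - W0)), 1e-8)

  # 8 training trials for 9 channels: underdetermined
  expect_error(fitWeights(matrix(0, 4, 8),
                          buildDesignMatrix(seq(0, 140, by = 20), b9)),
               "underdetermined")
  # rank-deficient C (duplicated single orientation)
  expect_error(fitWeights(matrix(rnorm(36), 4, 9),
                          buildDesignMatrix(rep(20, 9), b9)),
               "condition number")
})

test_that("model inversion equals the pseudoinverse oracle", {
  set.seed(1)
  W <- matrix(rnorm(12 * 5), 12, 5)
  c0 <- rnorm(5)
  expect_equal(drop(invertModel(W, W %*% c0)), c0, tolerance = 1e-8)
  expect_true(all(invertModel(W, matrix(0, 12, 4)) == 0))
  B <- matrix(rnorm(12 * 7), 12, 7)
  expect_equal(invertModel(W, B), pinvOracle(W) %*% B, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(invertModel(cbind(W[, 1], W[, 1]), B[, 1, drop = FALSE]),
               "condition number")
})

test_that("cross-validated encoding recovers tuned responses only where signal lives", {
  des <- smallDesign()
  cfg <- noiselessConfig()
  ep <- simulateEpochs(des, cfg)$epochs
  # signal support is [50, 470] ms after the second Gabor at 0.6 s
  ten <- encodeTimecourse(ep, stepMs = 16, timeRange = c(0.45, 1.05))
  cen <- centerResponses(ten)
  sel <- responseSelectivity(cen)
  tim <- timePoints(cen)
  expect_true(all(abs(sel[tim < 0.64]) < 1e-9))    # before onset: nothing
  # plateau: basis profile of unit mean amplitude, whose cosine projection
  # is its first Fourier coefficient 56/128
  inWin <- tim > 0.75 & tim < 0.82
  expect_equal(mean(sel[inWin]), 56 / 128, tolerance = 0.05)
  expect_true(all(sel[inWin] > 0.3))
  mid <- which(cen@offsets == 0)
  curve <- colMeans(channelResponses(cen)[, , which(inWin)[1]])
  expect_equal(which.max(curve), mid)
})

test_that("leave-one-out and 10-fold agree in the noiseless limit", {
  des <- smallDesign(nBlocks = 2, trialsPerBlock = 45)
  # uniform gain: the estimator is then independent of the training subset
  cfg <- noiselessConfig(gains = c(expected_repeat = 0.5,
                                   unexpected_repeat = 0.5,
                                   expected_alternate = 0.5,
                                   unexpected_alternate = 0.5))
  ep <- simulateEpochs(des, cfg)$epochs
  tA <- encodeTimecourse(ep, stepMs = 16, timeRange = c(0.75, 0.8),
                         cvScheme = "kfold", k = 10)
  tB <- encodeTimecourse(ep, stepMs = 16, timeRange = c(0.75, 0.8),
                         cvScheme = "loo")
  expect_equal(channelResponses(tA), channelResponses(tB),
               tolerance = 1e-6)
})

test_that("shuffling orientation labels destroys the centered response", {
  des <- smallDesign(nBlocks = 4)
  # sensor noise keeps the weight matrix well-conditioned once the
  # label-signal association is broken
  cfg <- noiselessConfig(noiseSdUV = 1)
  ep <- simulateEpochs(des, cfg)$epochs
  intact <- centerResponses(encodeTimecourse(ep, stepMs = 16,
                                             timeRange = c(0.75, 0.82)))
  aIntact <- fitTuningCurve(colMeans(channelResponses(intact)[, , 1]))$A
  shuf <- ep
  shuf@design$orientation_second <-
    withSeed(99, sample(shuf@design$orientation_second))
  ten <- centerResponses(encodeTimecourse(shuf, stepMs = 16,
                                          timeRange = c(0.75, 0.82)))
  aShuf <- fitTuningCurve(colMeans(channelResponses(ten)[, , 1]))$A
  expect_gt(aIntact, 0.5)
  expect_lt(abs(aShuf), 0.2 * aIntact)
})

test_that("centering puts the presented orientation at offset zero and permutes channels", {
  b <- makeBasis()
  des <- data.frame(
    session_id = 1L, block_id = 1L, block_type = "repeating",
    trial_type = "repeat", condition = "expected_repeat",
    orientation_first = seq(0, 160, by = 20),
    orientation_second = seq(0, 160, by = 20),
    is_target = FALSE, onset_second_s = 0.6)
  resp <- array(0, dim = c(9, 9, 2))
  for (i in 1:9) resp[i, , ] <- evalBasis(b, des$orientation_second[i])
  ten <- new("ChannelResponseTensor", responses = resp, centered = FALSE,
             timeAxis = c(0, 0.01), offsets = b@centers, design = des)
  cen <- centerResponses(ten)
  expect_true(cen@centered)
  expect_equal(cen@offsets, seq(-80, 80, by = 20))
  mid <- which(cen@offsets == 0)
  for (i in 1:9) {
    expect_equal(which.max(channelResponses(cen)[i, , 1]), mid)
    # permutation conserves the channel sum
    expect_equal(sum(channelResponses(cen)[i, , 1]),
                 sum(channelResponses(ten)[i, , 1]))
  }
  # the 9 orientations exercise all 9 cyclic rotations: uncentered peaks
  # cover every channel
  peaks <- vapply(1:9, function(i)
    which.max(channelResponses(ten)[i, , 1]), integer(1))
  expect_setequal(peaks, 1:9)
  expect_error(centerResponses(cen), "already centered")
})

test_that("rotating presented orientations rotates the mean uncentered response", {
  des <- smallDesign()
  cfg <- noiselessConfig(gains = c(expected_repeat = 0.5,
                                   unexpected_repeat = 0.5,
                                   expected_alternate = 0.5,
                                   unexpected_alternate = 0.5))
  ep <- simulateEpochs(des, cfg)$epochs
  base <- encodeTimecourse(ep, stepMs = 16, timeRange = c(0.76, 0.80))
  rot <- ep
  rot@design$orientation_second <- (rot@design$orientation_second + 20) %% 180
  # rotate the injected data accordingly: simulate afresh with rotated design
  rot@design$orientation_first <- ifelse(
    rot@design$trial_type == "repeat", rot@design$orientation_second,
    (rot@design$orientation_first + 20) %% 180)
  ep2 <- simulateEpochs(rot@design, cfg)$epochs
  rotTen <- encodeTimecourse(ep2, stepMs = 16, timeRange = c(0.76, 0.80))
  m1 <- colMeans(channelResponses(base)[, , 1])
  m2 <- colMeans(channelResponses(rotTen)[, , 1])
  expect_equal(m2, m1[c(9, 1:8)], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("no trial contributes to the weights that reconstruct it", {
  des <- smallDesign()
  folds <- makeFolds(des, k = 10)
  expect_length(folds, nrow(des))
  expect_true(all(folds >= 1 & folds <= 10))
  # every fold's training complement excludes exactly its own members
  for (f in unique(folds)) {
    expect_true(all(which(folds == f) %in% setdiff(seq_len(nrow(des)),
                                                   which(folds != f))))
  }
  # stratification: every training fold contains all 9 orientations
  for (f in unique(folds)) {
    tr <- des$orientation_second[folds != f]
    expect_length(unique(tr), 9)
  }
  # loo is one fold per trial
  expect_identical(makeFolds(des, scheme = "loo"), seq_len(nrow(des)))
})

test_that("cross-temporal generalisation is block-structured for a stable topography", {
  des <- smallDesign()
  cfg <- noiselessConfig()
  ep <- simulateEpochs(des, cfg)$epochs
  gm <- crossTemporalGeneralise(ep, stepMs = 32, timeRange = c(0.45, 1.05))
  tt <- gm@trainTimes
  inside <- tt > 0.72 & tt < 0.85          # envelope plateau
  before <- tt < 0.64
  expect_true(all(gm@selectivity[inside, inside] > 0.3))
  expect_true(all(abs(gm@selectivity[before, before]) < 1e-9))
  # diagonal consistency with the ordinary time course
  ten <- centerResponses(encodeTimecourse(ep, stepMs = 32,
                                          timeRange = c(0.45, 1.05)))
  sel <- responseSelectivity(ten)
  expect_equal(diag(gm@selectivity), sel, tolerance = 1e-6,
               ignore_attr = TRUE)
})
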