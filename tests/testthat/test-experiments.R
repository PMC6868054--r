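test_that("a sampling-experiment grid point equals the hand-composed DKL", {
  ssn <- buildSamplingNetwork(3, substrateSeed = 131)
  ssn <- setDigitalWeights(ssn, bias = c(2, -3, 1))
  tgt <- randomTarget(3, seed = 132)
  se <- samplingExperiment(ssn, tgt, duration = 5e3, grid = c(2e3, 5e3),
                           trialSeed = 133, noiseSeed = 134)
  run <- spikesampler:::ssnRun(ssn, duration = 5e3, trialSeed = 133,
                               noiseSeed = 134)
  st <- extractStates(run$spikes, 4, c(0, 2e3), ids = 1:3)
  expect_equal(se@metric[1], dkl(empiricalJoint(st), targetJoint(tgt)),
               tolerance = 1e-12)
  expect_equal(se@summary[["finalDkl"]], se@metric[2])
  # identical seeds reproduce the metric bit for bit
  se2 <- samplingExperiment(ssn, tgt, duration = 5e3, grid = c(2e3, 5e3),
                            trialSeed = 133, noiseSeed = 134)
  expect_identical(se@metric, se2@metric)
})

test_that("the cumulative DKL trace decreases in the median across seeds", {
  tgt <- randomTarget(4, seed = 141)
  tgt <- boltzmannTarget(targetWeights(tgt) * 0.5, targetBiases(tgt) * 0.5)
  ssn <- buildSamplingNetwork(4, substrateSeed = 142,
                              variability = variabilityModel(0, 0, 0))
  ssn <- calibrateNetwork(ssn, duration = 5e3, seed = 143)
  ssn <- translateParameters(ssn, tgt)
  grid <- round(exp(seq(log(500), log(5e4), length.out = 8)))
  traces <- vapply(1:6, function(s)
    samplingExperiment(ssn, tgt, duration = 5e4, grid = grid,
                       trialSeed = 150 + s, noiseSeed = 160 + s,
                       discretize = FALSE, variability = FALSE)@metric,
    numeric(length(grid)))
  med <- apply(traces, 1, median)
  # convergence trend over two decades: later values below earlier ones
  expect_lt(med[length(med)], med[1])
  expect_true(all(diff(med) < 0.05))
})

test_that("conditional inference evaluates the free subspace against the analytic conditional", {
  tgt <- randomTarget(5, seed = 171)
  ssn <- buildSamplingNetwork(5, substrateSeed = 172)
  res <- trainToTarget(ssn, tgt,
                       trainingConfig(iterations = 30L, samplingTimeMs = 5e3,
                                      seed = 173))
  ie <- inferenceExperiment(res$ssn, tgt, c("1" = 0, "2" = 1),
                            duration = 2e4, trialSeed = 174, noiseSeed = 175)
  # 2^3 free states for a 5-unit network with two clamped units
  expect_equal(ie@detail$free, 3:5)
  expect_gt(ie@detail$clampOccupancy[2], 0.9)
  expect_lt(ie@detail$clampOccupancy[1], 0.1)
  expect_true(all(is.finite(ie@metric)))
  expect_error(inferenceExperiment(res$ssn, tgt,
                                   stats::setNames(c(0, 1, 0, 1, 1), 1:5)),
               "clamp all")
})

test_that("an untrained network completes patterns at chance level", {
  ssn <- buildHierarchicalNetwork(nVisible = 144, nHidden = 8, nLabels = 2,
                                  substrateSeed = 181)
  set.seed(182)
  n <- nUnits(ssn)
  W <- matrix(0, n, n)
  W[ssn@pairs] <- runif(nrow(ssn@pairs), -15, 15)
  ssn <- setDigitalWeights(ssn, bias = runif(n, -15, 15),
                           coupling = (W + t(W)) / 2)
  imgs <- makeSyntheticDataset(2, 4, flipProb = 0, seed = 183)@images
  pc <- patternComplete(ssn, imgs[1:4, ], scheme = "saltpepper",
                        presentMs = 400, seed = 184, trialSeed = 185,
                        noiseSeed = 186)
  expect_equal(sum(pc@detail$masks[1, ]), 36)
  expect_equal(pc@summary[["longRunMse"]], 0.5, tolerance = 0.12)
})

test_that("guided dreaming enforces one-hot labels and class-specific images", {
  ds <- makeSyntheticDataset(3, 60, flipProb = 0.2, seed = 5)
  ssn <- buildHierarchicalNetwork(nLabels = 3, substrateSeed = 11)
  ssn <- calibrateNetwork(ssn, wbGrid = seq(-12, 12, by = 3),
                          duration = 2e3, seed = 13)
  pre <- pcdPretrain(ds, nHidden = 60, epochs = 30, weightDecay = 5e-4,
                     seed = 17)
  ssn1 <- spikesampler:::translateRBM(ssn, pre)
  gd <- guidedDream(ssn1, c(1, 2, 3, 2, 1, 3), perLabelMs = 800, seed = 31,
                    trialSeed = 71, noiseSeed = 76)
  # snapshot bookkeeping: entries x snapshots per segment
  expect_length(gd@times, 6 * (800 / 50))
  expect_equal(nrow(gd@detail$snapshots), length(gd@times))
  # enforced one-hot coding
  expect_true(all(gd@detail$labelOccupancy > 0.9))
  # class-conditional generation: thresholded mean images differ pairwise
  sn <- gd@detail$snapshots
  ml <- sapply(1:3, function(cl)
    colMeans(sn[gd@detail$snapshotLabel == cl, , drop = FALSE]))
  hd <- utils::combn(3, 2, function(ij)
    sum((ml[, ij[1]] > 0.5) != (ml[, ij[2]] > 0.5)))
  expect_true(all(hd > 0))
  expect_error(guidedDream(ssn1, c(1, 4)), "label units")
})

test_that("Poisson and random-network backends train to the same order of accuracy", {
  one <- function(noise, eta, its) {
    tgt <- randomTarget(5, seed = 191)
    ssn <- buildSamplingNetwork(5, noise = noise, substrateSeed = 192)
    res <- trainToTarget(ssn, tgt,
                         trainingConfig(eta = eta, iterations = its,
                                        samplingTimeMs = 1.5e4, seed = 193))
    run <- spikesampler:::ssnRun(res$ssn, duration = 1e5, trialSeed = 194,
                                 noiseSeed = 195)
    st <- extractStates(run$spikes, 4, c(80, 1e5), ids = 1:5)
    dkl(empiricalJoint(st), targetJoint(tgt))
  }
  dP <- one("poisson", 1.0, 150L)
  # the RN backend learns more slowly (background correlations must be
  # compensated) but reaches a comparable final divergence
  dR <- one("rn", 0.5, 250L)
  expect_lt(dR, 2 * dP)
})
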