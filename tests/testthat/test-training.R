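test_that("wake-sleep updates follow the moment-difference rule with momentum", {
  mk <- function(mz, mzz = matrix(0, length(mz), length(mz)))
    list(mz = mz, mzz = mzz)
  cfg <- trainingConfig(eta = 1.0, momentum = 0)
  # fixed point: matching statistics give zero updates
  up <- wakeSleepStep(mk(c(0.4, 0.6)), mk(c(0.4, 0.6)), cfg)
  expect_true(all(up$db == 0) && all(up$dW == 0))
  # direct rule
  up2 <- wakeSleepStep(mk(0.8), mk(0.3), cfg)
  expect_equal(up2$db, 0.5)
  # heavy-ball momentum recursion
  cfgM <- trainingConfig(eta = 1.0, momentum = 0.6)
  up3 <- wakeSleepStep(mk(0.8), mk(0.3), cfgM,
                       mom = list(db = 1.0, dW = matrix(0, 1, 1)))
  expect_equal(up3$db, 0.5 + 0.6 * 1.0)
  expect_error(wakeSleepStep(mk(c(0.5, 0.5)), mk(0.5), cfg), "length")
  expect_error(wakeSleepStep(mk(1.4), mk(0.3), cfg), "\\[0, 1\\]")
})

test_that("analytic wake statistics equal exact marginalization", {
  # independent units: second moments factorize
  b <- c(0.3, -1, 2)
  st <- analyticWakeStats(boltzmannTarget(matrix(0, 3, 3), b))
  expect_equal(st$mz, plogis(b), tolerance = 1e-12)
  expect_equal(st$mzz[1, 2], plogis(b[1]) * plogis(b[2]), tolerance = 1e-12)
  # uniform target
  su <- analyticWakeStats(boltzmannTarget(matrix(0, 2, 2), c(0, 0)))
  expect_equal(su$mz, c(0.5, 0.5))
  expect_equal(su$mzz[1, 2], 0.25)
  # random target vs a long Glauber run
  tgt <- randomTarget(5, seed = 61)
  sa <- analyticWakeStats(tgt)
  g <- glauberSample(tgt, sweeps = 2e5, seed = 62)
  expect_equal(sa$mz, g$mz, tolerance = 0.02)
  expect_equal(sa$mzz, g$mzz, tolerance = 0.03)
})

test_that("clamping inputs are phase-offset multapse trains that force the state", {
  ci <- clampInputs(c(1, 0), duration = 100)
  expect_equal(ci[[1]]$kind, "exc")
  expect_equal(ci[[2]]$kind, "inh")
  expect_length(ci[[1]]$trains, 5)
  expect_equal(ci[[1]]$trains[[1]][1:3], c(0, 10, 20))
  expect_equal(ci[[1]]$trains[[2]][1], 2)
  # zero duration: empty trains
  expect_true(all(lengths(clampInputs(1, 0)[[1]]$trains) == 0))
  # efficacy: clamped units sit at their target state
  ssn <- buildSamplingNetwork(2, substrateSeed = 71)
  run <- spikesampler:::ssnRun(ssn, duration = 5e3, trialSeed = 72,
                               noiseSeed = 73,
                               clampPattern = c("1" = 1, "2" = 0))
  occ <- unitOccupancy(run$spikes, 4, c(100, 5e3), ids = 1:2)
  expect_gt(occ[1], 0.9)
  expect_lt(occ[2], 0.1)
})

test_that("gradient sign: an underactive unit gets its bias weight increased", {
  wake <- list(mz = 0.9, mzz = matrix(0, 1, 1))
  model <- list(mz = 0.2, mzz = matrix(0, 1, 1))
  up <- wakeSleepStep(wake, model, trainingConfig(eta = 1))
  expect_gt(up$db, 0)
})

test_that("training toward a target reduces the sampled DKL and returns the best iterate", {
  res <- lapply(1:3, function(s) {
    tgt <- randomTarget(5, seed = 80 + s)
    ssn <- buildSamplingNetwork(5, substrateSeed = 90 + s)
    trainToTarget(ssn, tgt,
                  trainingConfig(iterations = 40L, samplingTimeMs = 5e3,
                                 seed = 100 + s))
  })
  for (r in res) {
    expect_equal(r$bestIteration, which.min(r$dklHistory))
    expect_equal(nrow(r$history), 40L)
  }
  final <- vapply(res, function(r) min(r$dklHistory), numeric(1))
  init <- vapply(res, function(r) r$dklHistory[1], numeric(1))
  # learning works at all: an order-of-magnitude drop even at this very
  # short protocol (40 iterations of 5e3 ms)
  expect_lt(median(final), median(init) / 5)
  expect_lt(median(final), 0.2)
})

test_that("wake-phase realization disables all couplings leaving the hidden layer", {
  ssn <- buildHierarchicalNetwork(nVisible = 144, nHidden = 4, nLabels = 2,
                                  substrateSeed = 111)
  n <- nUnits(ssn)
  W <- matrix(0, n, n)
  lay <- ssn@layout
  W[lay$visible[1], lay$hidden] <- 5
  W[lay$hidden, lay$visible[1]] <- 5
  W[lay$hidden, lay$label] <- -7
  W[lay$label, lay$hidden] <- -7
  ssn <- setDigitalWeights(ssn, coupling = (W + t(W)) / 2)
  wake <- realizeNetwork(ssn, disablePreUnits = lay$hidden)
  hiddenIds <- ssn@samplingIds[lay$hidden]
  plastic <- wake@synapses[wake@synapses$pre %in% hiddenIds &
                             !wake@synapses$post %in% hiddenIds, ]
  expect_equal(nrow(plastic), 0L)
  # the reverse direction (into the hidden layer) is untouched
  intoHidden <- wake@synapses[wake@synapses$post %in% hiddenIds, ]
  expect_gt(nrow(intoHidden), 0L)
  # disabling at realization equals manual removal of the same rows, so
  # wake-phase activity cannot depend on the turned-off couplings
  full <- realizeNetwork(ssn)
  manual <- full
  drop <- manual@synapses$pre %in% hiddenIds &
    !manual@synapses$post %in% hiddenIds
  manual@synapses <- manual@synapses[!drop, , drop = FALSE]
  rownames(manual@synapses) <- NULL
  o1 <- do.call(order, wake@synapses[, c("pre", "post", "kind")])
  o2 <- do.call(order, manual@synapses[, c("pre", "post", "kind")])
  expect_equal(wake@synapses[o1, ], manual@synapses[o2, ],
               ignore_attr = TRUE)
})

test_that("wake-sleep training recovers the moments of a generating model", {
  # data moments come from Glauber samples of a known 5-RV generator
  gen <- randomTarget(5, seed = 121)
  g <- glauberSample(gen, sweeps = 2e5, seed = 122)
  dataStats <- list(mz = g$mz, mzz = g$mzz)
  ssn <- buildSamplingNetwork(5, substrateSeed = 123)
  cfg <- trainingConfig(iterations = 50L, samplingTimeMs = 8e3, seed = 124)
  # manual loop with sampled wake statistics
  set.seed(1)
  w0 <- list(b = runif(5, -15, 15),
             W = {
               W <- matrix(0, 5, 5)
               W[upper.tri(W)] <- runif(10, -15, 15)
               W + t(W)
             })
  ssn <- setDigitalWeights(ssn, w0$b, w0$W)
  mom <- NULL
  gap <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    run <- spikesampler:::ssnRun(ssn, duration = cfg$samplingTimeMs,
                                 trialSeed = 1000 + it,
                                 noiseSeed = 2000 + it)
    model <- sampledMoments(run$spikes, 4, c(80, cfg$samplingTimeMs),
                            ids = 1:5)
    gap[it] <- max(abs(model$mz - dataStats$mz))
    up <- wakeSleepStep(dataStats, model, cfg, mom)
    mom <- up
    W <- ssn@couplingDigital + up$dW
    diag(W) <- 0
    ssn <- setDigitalWeights(ssn, pmin(pmax(ssn@biasDigital + up$db, -15), 15),
                             pmin(pmax((W + t(W)) / 2, -15), 15))
  }
  expect_lt(median(gap[41:50]), median(gap[1:10]))
  expect_lt(min(gap), 0.05)
})
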