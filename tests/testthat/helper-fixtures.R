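# Shared fixtures. Expensive objects (trained networks) are computed once
# per test session and memoised here; everything is fully seeded, so the
# suite is deterministic.

.fx <- new.env(parent = emptyenv())

memoFixture <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

childSeedForTest <- function(seed, stream)
  spikesampler:::childSeed(seed, stream)

# Median on-state occupancy of given units over a window.
unitOccupancy <- function(spikes, tauRef, window, ids) {
  st <- extractStates(spikes, tauRef, window, ids = ids)
  colSums(diff(st@breakpoints) * st@states) / diff(window)
}

# One full scaled-down training (200 iterations x 2e4 ms) plus a 1e5 ms
# test run, for one random 5-RV target. Returns history, best iteration and
# the test-run DKL. The workhorse behind the sampling benchmarks.
trainAndTest5 <- function(tseed, discretize = TRUE, iterations = 200L,
                          samplingTimeMs = 2e4, testMs = 1e5) {
  tgt <- randomTarget(5, seed = tseed)
  ssn <- buildSamplingNetwork(5, substrateSeed = 20 + tseed)
  cfg <- trainingConfig(eta = 1.0, momentum = 0.6, iterations = iterations,
                        samplingTimeMs = samplingTimeMs, seed = 30 + tseed)
  res <- trainToTarget(ssn, tgt, cfg, discretize = discretize)
  run <- spikesampler:::ssnRun(res$ssn, duration = testMs,
                trialSeed = 9e4 + tseed, noiseSeed = 9e4 + 17 * tseed,
                discretize = discretize)
  st <- extractStates(run$spikes, 4, c(80, testMs), ids = 1:5)
  list(target = tgt, result = res,
       testDkl = dkl(empiricalJoint(st), targetJoint(tgt)))
}

# The benchmark set: five target/seed combinations, 4-bit weights, default
# variability, private Poisson noise.
acceptanceRuns <- function() {
  memoFixture("acc5", lapply(1:5, trainAndTest5))
}

# Continuous-weight arm on the same targets and seeds.
acceptanceRunsContinuous <- function() {
  memoFixture("acc5cont", lapply(1:5, trainAndTest5, discretize = FALSE))
}

# Hierarchical data pipeline: synthetic dataset, calibration, PCD
# pre-training, translation, in-the-loop training.
hierPipeline <- function() {
  memoFixture("hier", {
    ds <- makeSyntheticDataset(3, 60, flipProb = 0.05, seed = 5)
    ssn <- buildHierarchicalNetwork(nLabels = 3, substrateSeed = 11)
    ssn <- calibrateNetwork(ssn, wbGrid = seq(-12, 12, by = 3),
                            duration = 2e3, seed = 13)
    pre <- pcdPretrain(ds, nHidden = 60, epochs = 30, seed = 17)
    ssn1 <- spikesampler:::translateRBM(ssn, pre)
    cfg <- trainingConfig(eta = 0.4, momentum = 0.6, iterations = 8L,
                          samplingTimeMs = 3e3, wakeTimeMs = 150,
                          minibatch = 7L, seed = 19)
    tr <- trainOnDataset(ssn1, ds, cfg)
    list(data = ds, calibrated = ssn, translated = ssn1,
         trained = tr$ssn, history = tr$history)
  })
}
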