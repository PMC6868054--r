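test_that("poissonTrain has Poisson counts and exponential intervals", {
  expect_length(poissonTrain(0, 1e4, seed = 1), 0)
  expect_length(poissonTrain(300, 0, seed = 1), 0)
  t1 <- poissonTrain(300, 1e5, seed = 2)
  expect_true(!is.unsorted(t1) && all(t1 >= 0) && all(t1 < 1e5))
  m <- 300 * 1e5 / 1000
  expect_lt(abs(length(t1) - m), 3 * sqrt(m))
  isi <- diff(poissonTrain(300, 4e4, seed = 3))
  expect_equal(sd(isi) / mean(isi), 1, tolerance = 0.05)
  expect_identical(poissonTrain(300, 1e3, seed = 4),
                   poissonTrain(300, 1e3, seed = 4))
  expect_error(poissonTrain(300, -1, seed = 1), "duration")
})

test_that("the random network is wired with exact in-degrees and no self-connections", {
  spec <- randomNetworkSpec()
  rn <- buildRandomNetwork(spec, samplingIds = 1:5, offset = 10,
                           unitScale = 2.8, seed = 5)
  rnIds <- 10 + seq_len(spec$nR)
  internal <- rn$synapses[rn$synapses$post %in% rnIds, ]
  expect_true(all(internal$kind == "inh"))
  expect_true(all(internal$pre != internal$post))
  expect_true(all(table(internal$post) == spec$kRN))
  # no duplicated inputs per RN neuron
  expect_false(anyDuplicated(internal[, c("pre", "post")]) > 0)
  proj <- rn$synapses[rn$synapses$post %in% 1:5, ]
  expect_true(all(table(proj$post, proj$kind) == spec$kNoise))
  expect_error(randomNetworkSpec(nR = 10, kRN = 10), "kRN")
})

test_that("RN neurons fire at the suprathreshold-leak rate once inhibition is removed", {
  spec <- randomNetworkSpec(nR = 50, kRN = 5)
  rn <- buildRandomNetwork(spec, samplingIds = integer(0), offset = 0,
                           unitScale = 2.8, seed = 6)
  syn <- rn$synapses
  syn$weight <- 0 * syn$weight
  net <- networkDefinition(rn$neurons, syn[FALSE, ])
  out <- simulateNetwork(net, duration = 2e3, dt = 0.05)
  rate <- 1000 * length(spikeTimes(out$spikes)) / 2e3 / 50
  expect_equal(rate, suprathresholdRate(rnNeuronParams())$rate,
               tolerance = 0.01)
})

test_that("the self-driven RN is stationary and asynchronous", {
  ssn <- buildSamplingNetwork(2, noise = "rn", substrateSeed = 7)
  run <- spikesampler:::ssnRun(ssn, duration = 2e4, noiseSeed = 1)
  rnIds <- ssn@noise$rnIds
  sp <- spikeTimes(run$spikes)[spikeIds(run$spikes) %in% rnIds]
  expect_gt(length(sp), 100)
  h1 <- sum(sp < 1e4); h2 <- sum(sp >= 1e4)
  expect_lt(abs(h2 / h1 - 1), 0.1)
})

test_that("an RN-driven unit has a logistic activation like the Poisson one", {
  ssn <- buildSamplingNetwork(1, noise = "rn", substrateSeed = 8,
                              variability = variabilityModel(0, 0, 0))
  act <- measureActivation(ssn, wbGrid = seq(-12, 12, by = 3),
                           duration = 4e3, seed = 9, variability = FALSE)
  f <- fitActivation(act$wb, act$rate)
  expect_true(is.finite(f@s) && f@s > 0)
  # width comparable to the Poisson backend's (overlapping curves)
  expect_gt(f@s, 1)
  expect_lt(f@s, 6)
})

test_that("noiseStatistics measures rates and pairwise count correlations", {
  t1 <- poissonTrain(200, 1e5, seed = 11)
  ns <- noiseStatistics(list(t1, t1), bin = 10, duration = 1e5)
  expect_equal(ns$correlations$rho, 1)
  expect_equal(ns$rates, c(200, 200), tolerance = 0.05)
  # independent sources decorrelated
  t2 <- poissonTrain(200, 1e5, seed = 12)
  ns2 <- noiseStatistics(list(t1, t2), bin = 10, duration = 1e5)
  expect_lt(abs(ns2$correlations$rho), 0.02)
  expect_error(noiseStatistics(list(t1), bin = 0), "bin")
})

test_that("shared RN input correlates sampling-neuron noise above the Poisson null", {
  ssn <- buildSamplingNetwork(4, noise = "rn", substrateSeed = 13)
  run <- spikesampler:::ssnRun(ssn, duration = 4e4, noiseSeed = 1)
  sp <- spikeTimes(run$spikes); id <- spikeIds(run$spikes)
  rnIds <- ssn@noise$rnIds
  # compare two RN projections' pooled input trains onto units 1 and 2
  proj <- ssn@net@synapses[ssn@net@synapses$post %in% ssn@samplingIds[1:2] &
                             ssn@net@synapses$kind == "exc", ]
  pooled <- lapply(ssn@samplingIds[1:2], function(u) {
    pres <- proj$pre[proj$post == u]
    sort(sp[id %in% pres])
  })
  nsRN <- noiseStatistics(pooled, bin = 10, duration = 4e4)
  ind <- lapply(1:2, function(k) poissonTrain(nsRN$rates[k], 4e4,
                                              seed = 20 + k))
  nsInd <- noiseStatistics(ind, bin = 10, duration = 4e4)
  expect_gt(nsRN$correlations$rho, nsInd$correlations$rho)
})
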