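test_that("a neuron at its leak equilibrium stays silent and constant", {
  net <- networkDefinition(samplingNeuronParams())
  out <- simulateNetwork(net, duration = 100, dt = 0.1, record = 1L,
                         u0 = -20)
  expect_length(spikeTimes(out$spikes), 0)
  expect_true(all(out$traces == -20))
})

test_that("without input the membrane relaxes exponentially toward E_leak", {
  # subthreshold neuron (leak below threshold) started away from rest
  p <- neuronParameters(E_leak = -60, V_thresh = -20, V_reset = -70)
  net <- networkDefinition(p)
  dt <- 0.05
  out <- simulateNetwork(net, duration = 40, dt = dt, record = 1L, u0 = -40)
  tt <- attr(out$traces, "times")
  expected <- -60 + (-40 + 60) * exp(-tt / 7)
  # exponential Euler reproduces a pure exponential on the grid exactly
  expect_lt(max(abs(out$traces[1, ] - expected)), 1e-9)
})

test_that("suprathreshold-leak firing matches the closed-form ISI oracle and converges in dt", {
  oracle <- suprathresholdRate(biasNeuronParams())$isi
  isiAt <- function(dt) {
    out <- simulateNetwork(networkDefinition(biasNeuronParams()),
                           duration = 500, dt = dt)
    mean(diff(spikeTimes(out$spikes)))
  }
  errCoarse <- abs(isiAt(0.1) - oracle) / oracle
  errFine <- abs(isiAt(0.025) - oracle) / oracle
  expect_lt(errFine, 0.01)
  expect_lt(errFine, errCoarse)
})

test_that("the membrane is clamped to V_reset during every refractory window", {
  net <- networkDefinition(biasNeuronParams())
  dt <- 0.05
  out <- simulateNetwork(net, duration = 100, dt = dt, record = 1L)
  tt <- attr(out$traces, "times")
  tr <- out$traces[1, ]
  for (tsp in spikeTimes(out$spikes)) {
    inRef <- tt >= tsp - 1e-9 & tt < tsp + 1.5 - 1e-9
    expect_true(all(tr[inRef] == -30))
  }
})

test_that("a delayed synaptic input produces its PSP only after onset", {
  p <- neuronParameters(E_leak = -60, V_thresh = -20, V_reset = -70)
  ext <- data.frame(port = "in", post = 1L, weight = 5, kind = "exc",
                    delay = 1, stringsAsFactors = FALSE)
  net <- networkDefinition(p, extSynapses = ext)
  base <- simulateNetwork(net, duration = 20, dt = 0.1, record = 1L,
                          u0 = -60)
  out <- simulateNetwork(net, inputs = list(`in` = 5), duration = 20,
                         dt = 0.1, record = 1L, u0 = -60)
  tt <- attr(out$traces, "times")
  expect_equal(out$traces[1, tt <= 6], base$traces[1, tt <= 6])
  expect_true(all(out$traces[1, tt > 6.05 & tt < 12] >
                    base$traces[1, tt > 6.05 & tt < 12]))
})

test_that("conductanceAt follows the exponential kernel with delay and superposition", {
  expect_identical(conductanceAt(5.9, spikes = 5, J = 2, tauSyn = 8,
                                 delay = 1), 0)
  expect_equal(conductanceAt(6, spikes = 5, J = 2, tauSyn = 8, delay = 1), 2)
  expect_equal(conductanceAt(6 + 8, spikes = 5, J = 2, tauSyn = 8,
                             delay = 1), 2 / exp(1))
  # kernels of successive spikes superpose linearly
  g2 <- conductanceAt(10, spikes = c(3, 5), J = 2, tauSyn = 8, delay = 1)
  expect_equal(g2, conductanceAt(10, 3, 2, 8, 1) + conductanceAt(10, 5, 2, 8, 1))
  expect_identical(conductanceAt(10, numeric(), 2, 8, 1), 0)
})

test_that("simulation is bit-for-bit deterministic for identical inputs", {
  ssn <- buildSamplingNetwork(3, substrateSeed = 4)
  ssn <- setDigitalWeights(ssn, bias = c(2, -1, 0),
                           coupling = {
                             W <- matrix(0, 3, 3)
                             W[1, 2] <- W[2, 1] <- 3
                             W
                           })
  r1 <- spikesampler:::ssnRun(ssn, duration = 2e3, trialSeed = 7,
                              noiseSeed = 8)
  r2 <- spikesampler:::ssnRun(ssn, duration = 2e3, trialSeed = 7,
                              noiseSeed = 8)
  expect_identical(spikeTimes(r1$spikes), spikeTimes(r2$spikes))
  expect_identical(spikeIds(r1$spikes), spikeIds(r2$spikes))
})

test_that("invalid simulation requests are rejected with an explanation", {
  net <- networkDefinition(samplingNeuronParams())
  expect_error(simulateNetwork(net, duration = 10, dt = 2), "too coarse")
  expect_error(simulateNetwork(net, inputs = list(bogus = c(1, 2)),
                               duration = 10), "unknown input port")
  expect_error(simulateNetwork(net, duration = -5), "duration")
})
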