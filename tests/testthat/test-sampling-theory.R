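test_that("target joints match closed forms and brute-force enumeration", {
  # independent uniform case
  p <- targetJoint(boltzmannTarget(matrix(0, 2, 2), c(0, 0)))
  expect_equal(probs(p), rep(0.25, 4))
  # single unit: p(z=1) = sigmoid(b)
  p1 <- targetJoint(boltzmannTarget(matrix(0, 1, 1), log(3)))
  expect_equal(probs(p1), c(0.25, 0.75))
  # coupled pair: p(1,1) = e / (3 + e)
  W <- matrix(c(0, 1, 1, 0), 2)
  p2 <- targetJoint(boltzmannTarget(W, c(0, 0)))
  expect_equal(probs(p2)[4], exp(1) / (3 + exp(1)))
  # independent brute-force oracle for a random 4-RV target
  tgt <- randomTarget(4, seed = 9)
  Z <- stateMatrix(4)
  e <- apply(Z, 1, function(z)
    0.5 * sum(z * (targetWeights(tgt) %*% z)) + sum(z * targetBiases(tgt)))
  expect_equal(probs(targetJoint(tgt)), exp(e) / sum(exp(e)))
})

test_that("conditioning slices and renormalizes the joint correctly", {
  tgt <- randomTarget(5, seed = 3)
  # empty clamp is the identity
  expect_equal(probs(conditionalJoint(tgt, NULL)), probs(targetJoint(tgt)))
  # brute-force renormalization oracle for clamp (z1, z2) = (0, 1)
  full <- probs(targetJoint(tgt))
  Z <- stateMatrix(5)
  sel <- Z[, 1] == 0 & Z[, 2] == 1
  cond <- conditionalJoint(tgt, c("1" = 0, "2" = 1))
  expect_equal(nUnits(cond), 3L)
  expect_equal(probs(cond), full[sel] / sum(full[sel]))
  # with W = 0 the free units keep their independent marginals
  b <- c(-0.5, 0.2, 1.1)
  ind <- boltzmannTarget(matrix(0, 3, 3), b)
  ci <- conditionalJoint(ind, c("2" = 1))
  m <- tableMoments(ci)$mz
  expect_equal(m, plogis(b[c(1, 3)]), tolerance = 1e-12)
})

test_that("refractory state extraction forms unions of on-windows", {
  st <- extractStates(spikeTrain(10, 1L, duration = 20), 4, c(0, 20))
  expect_equal(st@breakpoints, c(0, 10, 14, 20))
  expect_equal(as.vector(st@states), c(0L, 1L, 0L))
  # overlapping refractory windows merge
  st2 <- extractStates(spikeTrain(c(10, 12), c(1L, 1L), duration = 20), 4,
                       c(0, 20))
  expect_equal(st2@breakpoints, c(0, 10, 16, 20))
  expect_equal(as.vector(st2@states), c(0L, 1L, 0L))
  # no spikes: all-zero state over the whole window
  st3 <- extractStates(spikeTrain(duration = 20), 4, c(0, 20), ids = 1:2)
  expect_equal(nrow(st3@states), 1L)
  expect_true(all(st3@states == 0L))
  expect_error(extractStates(spikeTrain(10, 1L, duration = 20), 4,
                             c(0, 50)), "outside")
})

test_that("the empirical joint is the time-weighted state histogram", {
  st <- extractStates(spikeTrain(10, 1L, duration = 20), 4, c(0, 20))
  expect_equal(probs(empiricalJoint(st)), c(0.8, 0.2))
  # two states each occupying half the window
  stHalf <- new("StateSequence", breakpoints = c(0, 5, 10),
                states = matrix(c(0L, 1L), 2, 1))
  expect_equal(probs(empiricalJoint(stHalf)), c(0.5, 0.5))
  # occupancy identity p(z = 1) = nu * tau_ref for an isolated neuron
  ssn <- buildSamplingNetwork(1, substrateSeed = 2,
                              variability = variabilityModel(0, 0, 0))
  ssn <- setDigitalWeights(ssn, bias = -2)
  run <- spikesampler:::ssnRun(ssn, duration = 5e4, noiseSeed = 6,
                               discretize = FALSE, variability = FALSE)
  nSp <- sum(spikeIds(run$spikes) == 1)
  occ <- probs(empiricalJoint(extractStates(run$spikes, 4, c(0, 5e4),
                                            ids = 1L)))[2]
  expect_equal(occ, nSp * 4 / 5e4, tolerance = 0.01)
})

test_that("dkl matches its definition and is non-negative", {
  expect_equal(dkl(probabilityTable(c(1, 0)), probabilityTable(c(.5, .5))),
               log(2))
  tgt <- randomTarget(5, seed = 12)
  p <- targetJoint(tgt)
  expect_equal(dkl(p, p), 0)
  # per-state summation oracle on a random pair of 5-RV tables
  q <- targetJoint(randomTarget(5, seed = 13))
  byHand <- sum(probs(p) * log(probs(p) / probs(q)))
  expect_equal(dkl(p, q), byHand, tolerance = 1e-12)
  expect_gte(dkl(p, q), 0)
  expect_error(dkl(probabilityTable(c(.5, .5)), probabilityTable(c(1, 0))),
               "zero probability")
})

test_that("random targets follow the shifted-Beta scheme", {
  tgt <- randomTarget(6, seed = 44)
  W <- targetWeights(tgt)
  expect_true(all(abs(W) <= 1))
  expect_true(all(abs(targetBiases(tgt)) <= 1))
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
  draws <- unlist(lapply(1:400, function(s)
    targetBiases(randomTarget(5, seed = s))))
  expect_lt(abs(mean(draws)), 0.05)
  # U-shape: mass piles up near the edges relative to the center
  expect_gt(mean(abs(draws) > 0.8), mean(abs(draws) < 0.2))
  # reproducibility
  expect_identical(randomTarget(5, seed = 7), randomTarget(5, seed = 7))
})

test_that("probability tables stay normalized through the operations", {
  for (s in 1:5) {
    tgt <- randomTarget(4, seed = s)
    expect_equal(sum(probs(targetJoint(tgt))), 1, tolerance = 1e-12)
    expect_equal(sum(probs(conditionalJoint(tgt, c("1" = 1)))), 1,
                 tolerance = 1e-12)
  }
})

test_that("marginals of an unclamped conditional equal the target marginals", {
  tgt <- randomTarget(5, seed = 21)
  expect_equal(tableMoments(conditionalJoint(tgt, NULL))$mz,
               tableMoments(targetJoint(tgt))$mz, tolerance = 1e-12)
})

test_that("Glauber dynamics converges to the target joint", {
  tgt <- randomTarget(5, seed = 31)
  g <- glauberSample(tgt, sweeps = 2e5, burnin = 1000, seed = 8)
  expect_lt(dkl(g$p, targetJoint(tgt)), 5e-3)
  # moments agree with enumeration
  mom <- tableMoments(targetJoint(tgt))
  expect_equal(g$mz, mom$mz, tolerance = 0.02)
  expect_equal(g$mzz, mom$mzz, tolerance = 0.03)
})

test_that("sampledMoments agrees with the explicit state-table moments", {
  ssn <- buildSamplingNetwork(4, substrateSeed = 14)
  W <- matrix(0, 4, 4); W[1, 3] <- W[3, 1] <- 5; W[2, 4] <- W[4, 2] <- -4
  ssn <- setDigitalWeights(ssn, bias = c(1, -1, 0, 2), coupling = W)
  run <- spikesampler:::ssnRun(ssn, duration = 5e3, trialSeed = 3,
                               noiseSeed = 4)
  st <- extractStates(run$spikes, 4, c(0, 5e3), ids = 1:4)
  momTable <- tableMoments(empiricalJoint(st))
  momDirect <- sampledMoments(run$spikes, 4, c(0, 5e3), ids = 1:4)
  expect_equal(momDirect$mz, momTable$mz, tolerance = 1e-9)
  expect_equal(momDirect$mzz, momTable$mzz, tolerance = 1e-9)
})
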