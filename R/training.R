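#' Training configuration
#'
#' Bundles the wake-sleep in-the-loop training parameters: learning rate
#' (digital weight units per unit of moment mismatch), heavy-ball momentum
#' factor, iteration count, sampling (sleep-phase) time per iteration and
#' the master seed from which all per-iteration streams (trial rewrites,
#' noise) are derived. For data-driven training, \code{minibatch} images per
#' class are drawn per iteration and \code{wakeTimeMs} is the clamped
#' sampling time per image.
#'
#' @param eta learning rate (> 0).
#' @param momentum momentum factor in \code{[0, 1)}.
#' @param iterations number of training iterations (>= 1).
#' @param samplingTimeMs sleep-phase sampling time per iteration, ms.
#' @param burnInMs initial sleep-phase time discarded before measuring
#'   moments (default ten synaptic time constants).
#' @param minibatch images per class per iteration (data training only).
#' @param wakeTimeMs clamped sampling time per wake-phase image, ms.
#' @param seed master training seed.
#' @return a list with class \code{"trainingConfig"}.
#' @export
trainingConfig <- function(eta = 1.0, momentum = 0.6, iterations = 200L,
                           samplingTimeMs = 2e4, burnInMs = 80,
                           minibatch = 7L, wakeTimeMs = 200, seed = 1L) {
  stopifnot(eta > 0, momentum >= 0, momentum < 1, iterations >= 1,
            samplingTimeMs > burnInMs)
  structure(list(eta = eta, momentum = momentum,
                 iterations = as.integer(iterations),
                 samplingTimeMs = samplingTimeMs, burnInMs = burnInMs,
                 minibatch = as.integer(minibatch), wakeTimeMs = wakeTimeMs,
                 seed = as.integer(seed)),
            class = "trainingConfig")
}

#' One wake-sleep parameter update
#'
#' Computes the wake-sleep updates
#' \deqn{\Delta b_i = \eta(\langle z_i\rangle^* - \langle z_i\rangle), \quad
#'   \Delta W_{ij} = \eta(\langle z_i z_j\rangle^* -
#'   \langle z_i z_j\rangle)}
#' augmented with heavy-ball momentum:
#' \eqn{\Delta_t = \eta\,g_t + m\,\Delta_{t-1}}.
#'
#' @param dataStats list with \code{mz}, \code{mzz}: wake (data/target)
#'   moments.
#' @param modelStats list with \code{mz}, \code{mzz}: sleep (model) moments.
#' @param cfg a [trainingConfig()].
#' @param mom previous update (list with \code{db}, \code{dW}) or
#'   \code{NULL} for a zero momentum state.
#' @return list with \code{db}, \code{dW} (the applied updates, which are
#'   also the next momentum state).
#' @export
#' @examples
#' up <- wakeSleepStep(list(mz = 0.8, mzz = matrix(0, 1, 1)),
#'                     list(mz = 0.3, mzz = matrix(0, 1, 1)),
#'                     trainingConfig(eta = 1), mom = NULL)
#' up$db  # 0.5
wakeSleepStep <- function(dataStats, modelStats, cfg, mom = NULL) {
  stopifnot(length(dataStats$mz) == length(modelStats$mz),
            all(dim(dataStats$mzz) == dim(modelStats$mzz)))
  rng <- range(c(dataStats$mz, modelStats$mz, dataStats$mzz,
                 modelStats$mzz))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stopf("moment statistics must lie in [0, 1]")
  n <- length(dataStats$mz)
  if (is.null(mom)) mom <- list(db = numeric(n), dW = matrix(0, n, n))
  db <- cfg$eta * (dataStats$mz - modelStats$mz) + cfg$momentum * mom$db
  dW <- cfg$eta * (dataStats$mzz - modelStats$mzz) + cfg$momentum * mom$dW
  diag(dW) <- 0
  list(db = db, dW = dW)
}

#' Analytic wake statistics of a Boltzmann target
#'
#' For fully specified low-dimensional targets the wake term of the
#' wake-sleep rule needs no sampling: \eqn{\langle z_i\rangle^* = p^*(z_i=1)}
#' and \eqn{\langle z_i z_j\rangle^* = p^*(z_i=1, z_j=1)} by explicit
#' marginalization of the target joint.
#'
#' @param target a [BoltzmannTarget-class] (n <= 20).
#' @return list with \code{mz} and \code{mzz}.
#' @export
analyticWakeStats <- function(target) tableMoments(targetJoint(target))

#' Clamping input spike trains
#'
#' Clamping forces a neuron's state: each clamped neuron receives a 5-fold
#' multapse of regular 100 Hz spike trains, excitatory for target state 1
#' and inhibitory for target state 0. The five trains are phase-offset by
#' 2 ms (one fifth of the 10 ms period) to smooth the clamping conductance.
#'
#' @param pattern 0/1 vector of target states, one per clamped neuron.
#' @param duration train length, ms.
#' @param rate per-train rate, Hz.
#' @param multapse number of parallel synapses/trains per clamped neuron.
#' @return list (one element per clamped neuron) with elements \code{kind}
#'   ("exc" or "inh") and \code{trains} (list of spike time vectors).
#' @export
#' @examples
#' ci <- clampInputs(c(1, 0), duration = 50)
#' ci[[1]]$kind  # "exc"
clampInputs <- function(pattern, duration, rate = 100, multapse = 5L) {
  if (duration < 0) stopf("duration must be >= 0")
  period <- 1000 / rate
  offsets <- (seq_len(multapse) - 1L) * period / multapse
  lapply(as.integer(pattern), function(z) {
    list(kind = if (z == 1L) "exc" else "inh",
         trains = lapply(offsets, function(o)
           if (duration > o) seq(o, duration - 1e-9, by = period)
           else numeric()))
  })
}

# Named port -> spike-times list matching addClampPorts() naming, for
# clamping the given network neurons to the given 0/1 pattern starting at
# time `from`.
clampPortInputs <- function(neuronIds, pattern, duration, from = 0,
                            rate = 100, multapse = 5L) {
  ci <- clampInputs(pattern, duration - from, rate = rate,
                    multapse = multapse)
  out <- list()
  for (k in seq_along(neuronIds)) {
    kindChr <- substr(ci[[k]]$kind, 1, 1)
    for (m in seq_len(multapse)) {
      out[[sprintf("clamp_%s_%d_%d", kindChr, neuronIds[k], m)]] <-
        ci[[k]]$trains[[m]] + from
    }
  }
  out
}

#' Wake-sleep in-the-loop training toward a target distribution
#'
#' Trains a sampling network to represent a fully specified Boltzmann
#' target. Per iteration: the digital weights are written to the substrate
#' (4-bit discretization plus a fresh trial-to-trial rewrite), the free
#' network samples for the configured sleep time, time-weighted model
#' moments and the sampled-vs-target DKL are measured, and the continuous
#' shadow weights are updated by [wakeSleepStep()] against the analytic wake
#' statistics. The result is the parameter configuration with the best
#' (lowest) DKL observed during training — under discretization the final
#' iteration is often not the best one, as training oscillates between
#' adjacent integer weights.
#'
#' @param ssn a [SamplingNetwork-class] with \code{nUnits(ssn)} units.
#' @param target the [BoltzmannTarget-class] to learn.
#' @param cfg a [trainingConfig()].
#' @param discretize 4-bit weight discretization on/off.
#' @param variability substrate variability on/off.
#' @param dt integration step, ms.
#' @param init initial digital weights: \code{"uniform"} draws all biases
#'   and couplings from U(-15, 15); \code{"keep"} starts from the weights in
#'   \code{ssn}.
#' @return list with \code{ssn} (trained network, best weights installed),
#'   \code{dklHistory} (per-iteration DKL, nats), \code{bestIteration},
#'   \code{history} (data.frame: iteration, dkl, bias/coupling norms).
#' @export
trainToTarget <- function(ssn, target, cfg = trainingConfig(),
                          discretize = TRUE, variability = TRUE, dt = 0.1,
                          init = c("uniform", "keep")) {
  stopifnot(is(ssn, "SamplingNetwork"), is(target, "BoltzmannTarget"))
  init <- match.arg(init)
  n <- nUnits(ssn)
  if (nUnits(target) != n)
    stopf("target size (%d) must match the network (%d units)",
          nUnits(target), n)
  wake <- analyticWakeStats(target)
  pJoint <- targetJoint(target)
  tauRef <- ssn@net@neurons$tau_ref[ssn@samplingIds]

  if (init == "uniform") {
    w0 <- withSeed(childSeed(cfg$seed, 1L), {
      b <- stats::runif(n, -15, 15)
      W <- matrix(0, n, n)
      W[ssn@pairs] <- stats::runif(nrow(ssn@pairs), -15, 15)
      list(b = b, W = W + t(W))
    })
    ssn <- setDigitalWeights(ssn, w0$b, w0$W)
  }

  mom <- NULL
  dklHist <- numeric(cfg$iterations)
  bestDkl <- Inf
  best <- list(b = ssn@biasDigital, W = ssn@couplingDigital)
  hist <- vector("list", cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    run <- ssnRun(ssn, duration = cfg$samplingTimeMs, dt = dt,
                  trialSeed = childSeed(cfg$seed, 1000L + it),
                  noiseSeed = childSeed(cfg$seed, 2000L + it),
                  discretize = discretize, variability = variability)
    st <- extractStates(run$spikes, tauRef,
                        window = c(cfg$burnInMs, cfg$samplingTimeMs),
                        ids = ssn@samplingIds)
    emp <- empiricalJoint(st)
    model <- tableMoments(emp)
    dklHist[it] <- dkl(emp, pJoint)
    if (dklHist[it] < bestDkl) {
      bestDkl <- dklHist[it]
      best <- list(b = ssn@biasDigital, W = ssn@couplingDigital)
    }
    upd <- wakeSleepStep(wake, model, cfg, mom)
    mom <- upd
    newB <- pmin(pmax(ssn@biasDigital + upd$db, -15), 15)
    newW <- pmin(pmax(ssn@couplingDigital + upd$dW, -15), 15)
    W <- matrix(0, n, n)
    W[ssn@pairs] <- newW[ssn@pairs]
    ssn <- setDigitalWeights(ssn, newB, W + t(W))
    hist[[it]] <- data.frame(iteration = it, dkl = dklHist[it],
                             biasNorm = sqrt(mean(ssn@biasDigital^2)),
                             couplingNorm = sqrt(mean(
                               ssn@couplingDigital[ssn@pairs]^2)))
  }
  ssn <- setDigitalWeights(ssn, best$b, best$W)
  list(ssn = ssn, dklHistory = dklHist,
       bestIteration = which.min(dklHist),
       history = do.call(rbind, hist))
}

#' Persistent-contrastive-divergence pre-training of an RBM
#'
#' Standard PCD training of a restricted Boltzmann machine over (visible +
#' label, hidden) units, used to initialize hierarchical sampling networks
#' before in-the-loop training. Conditioned on the hidden layer, visible
#' and label units are independent, so the three-layer architecture is an
#' RBM with the label units appended to the visible layer.
#'
#' @param data an [ImageDataset-class]; training uses its "train" split.
#' @param nHidden hidden layer size.
#' @param epochs full passes over the training set.
#' @param eta learning rate.
#' @param weightDecay L2 penalty on the weights. Keeps the generative model
#'   soft enough to mix between class modes (and the translated digital
#'   weights inside the 4-bit range); without it, easily separable data
#'   grows weights that freeze the network into one attractor.
#' @param nChains persistent fantasy chains.
#' @param batchSize minibatch size.
#' @param seed integer seed.
#' @return list with \code{W} ((144+L) x nHidden weights), \code{bv}
#'   (visible+label biases), \code{bh} (hidden biases), in natural
#'   (dimensionless Boltzmann) units.
#' @export
pcdPretrain <- function(data, nHidden = 60, epochs = 30, eta = 0.05,
                        weightDecay = 2e-3, nChains = 50, batchSize = 20,
                        seed = 1L) {
  stopifnot(is(data, "ImageDataset"))
  tr <- data@split == "train"
  X <- data@images[tr, , drop = FALSE]
  L <- data@nClasses
  lab <- matrix(0, nrow(X), L)
  lab[cbind(seq_len(nrow(X)), data@labels[tr])] <- 1
  V <- cbind(X, lab)
  nv <- ncol(V)
  sigmoid <- function(x) 1 / (1 + exp(-x))
  withSeed(seed, {
    W <- matrix(stats::rnorm(nv * nHidden, sd = 0.01), nv, nHidden)
    bv <- numeric(nv)
    bh <- numeric(nHidden)
    chains <- matrix(stats::runif(nChains * nv) < 0.5, nChains, nv) * 1
    for (ep in seq_len(epochs)) {
      idx <- sample(nrow(V))
      for (b in split(idx, ceiling(seq_along(idx) / batchSize))) {
        vb <- V[b, , drop = FALSE]
        ph <- sigmoid(sweep(vb %*% W, 2, bh, "+"))
        # persistent chains: one Gibbs step
        hh <- (sigmoid(sweep(chains %*% W, 2, bh, "+")) >
                 stats::runif(nChains * nHidden)) * 1
        pv <- sigmoid(sweep(hh %*% t(W), 2, bv, "+"))
        chains <- (pv > stats::runif(nChains * nv)) * 1
        phc <- sigmoid(sweep(chains %*% W, 2, bh, "+"))
        W <- W + eta * (crossprod(vb, ph) / nrow(vb) -
                          crossprod(chains, phc) / nChains -
                          weightDecay * W)
        bv <- bv + eta * (colMeans(vb) - colMeans(chains))
        bh <- bh + eta * (colMeans(ph) - colMeans(phc))
      }
    }
    list(W = W, bv = bv, bh = bh)
  })
}

#' Wake-sleep in-the-loop training on image data
#'
#' Trains a hierarchical sampling network on labeled binary images. Wake
#' phase: for each minibatch image, visible and label neurons are clamped
#' (excitatory multapse for 1-pixels / the true label, inhibitory for
#' 0-pixels / other labels) while the plastic synapses leaving the hidden
#' layer are turned off, and moments are measured from the spiking
#' activity. Sleep phase: the network runs free and time-weighted moments
#' are measured. Updates follow [wakeSleepStep()] per allowed pair, weights
#' are rediscretized and rewritten (fresh trial seed) each iteration.
#'
#' @param ssn a hierarchical [SamplingNetwork-class] (see
#'   [buildHierarchicalNetwork()]).
#' @param data an [ImageDataset-class]; minibatches are drawn from its
#'   train split.
#' @param cfg a [trainingConfig()].
#' @param discretize,variability,dt as in [trainToTarget()].
#' @return list with \code{ssn} (trained network, final weights),
#'   \code{history} (data.frame: iteration, momentGap = mean absolute
#'   wake-sleep moment mismatch over plastic parameters).
#' @export
trainOnDataset <- function(ssn, data, cfg = trainingConfig(eta = 0.4,
                                                           iterations = 20L),
                           discretize = TRUE, variability = TRUE, dt = 0.1) {
  stopifnot(is(ssn, "SamplingNetwork"), is(data, "ImageDataset"),
            ssn@layout$type == "hierarchical")
  lay <- ssn@layout
  if (length(lay$visible) != ncol(data@images))
    stopf("image size (%d) must match the visible layer (%d)",
          ncol(data@images), length(lay$visible))
  if (data@nClasses > length(lay$label))
    stopf("more classes than label units")
  n <- nUnits(ssn)
  tauRef <- ssn@net@neurons$tau_ref[ssn@samplingIds]
  tr <- which(data@split == "train")
  mom <- NULL
  hist <- vector("list", cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    batch <- withSeed(childSeed(cfg$seed, 3000L + it), {
      unlist(lapply(seq_len(data@nClasses), function(cl) {
        pool <- tr[data@labels[tr] == cl]
        sample(pool, min(cfg$minibatch, length(pool)))
      }), use.names = FALSE)
    })
    # wake phase: clamp visible + label, top-down couplings off
    wakeBurn <- cfg$burnInMs
    wakeAcc <- list(mz = numeric(n), mzz = matrix(0, n, n))
    for (im in batch) {
      pat <- c(data@images[im, ],
               as.integer(seq_along(lay$label) == data@labels[im]))
      names(pat) <- c(lay$visible, lay$label)
      run <- ssnRun(ssn, duration = wakeBurn + cfg$wakeTimeMs, dt = dt,
                    trialSeed = childSeed(cfg$seed, 1000L + it),
                    noiseSeed = childSeed(cfg$seed, 4000L + 37L * it + im),
                    discretize = discretize, variability = variability,
                    clampPattern = pat, disablePreUnits = lay$hidden)
      mo <- sampledMoments(run$spikes, tauRef,
                           window = c(wakeBurn, wakeBurn + cfg$wakeTimeMs),
                           ids = ssn@samplingIds, pairs = ssn@pairs)
      wakeAcc$mz <- wakeAcc$mz + mo$mz
      wakeAcc$mzz <- wakeAcc$mzz + mo$mzz
    }
    wake <- list(mz = wakeAcc$mz / length(batch),
                 mzz = wakeAcc$mzz / length(batch))
    # sleep phase: free run
    run <- ssnRun(ssn, duration = cfg$samplingTimeMs, dt = dt,
                  trialSeed = childSeed(cfg$seed, 1000L + it),
                  noiseSeed = childSeed(cfg$seed, 5000L + it),
                  discretize = discretize, variability = variability)
    model <- sampledMoments(run$spikes, tauRef,
                            window = c(cfg$burnInMs, cfg$samplingTimeMs),
                            ids = ssn@samplingIds, pairs = ssn@pairs)
    upd <- wakeSleepStep(wake, model, cfg, mom)
    mom <- upd
    newB <- pmin(pmax(ssn@biasDigital + upd$db, -15), 15)
    W <- matrix(0, n, n)
    W[ssn@pairs] <- pmin(pmax((ssn@couplingDigital + upd$dW)[ssn@pairs],
                              -15), 15)
    ssn <- setDigitalWeights(ssn, newB, W + t(W))
    hist[[it]] <- data.frame(
      iteration = it,
      momentGap = mean(abs(c(wake$mz - model$mz,
                             (wake$mzz - model$mzz)[ssn@pairs]))))
  }
  list(ssn = ssn, history = do.call(rbind, hist))
}
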