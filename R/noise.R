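#' Poisson background spike trains
#'
#' Homogeneous Poisson process of the given rate, the ideal noise backend
#' that renders sampling neurons stochastic and drives them into the
#' high-conductance state. Seeded and reproducible.
#'
#' @param rate rate in Hz (>= 0).
#' @param duration train length, ms (>= 0).
#' @param seed integer seed.
#' @return numeric vector of spike times in ms (empty for rate 0).
#' @export
#' @examples
#' length(poissonTrain(300, 1e4, seed = 1))  # ~3000
poissonTrain <- function(rate, duration, seed) {
  stopifnot(rate >= 0)
  if (duration < 0) stopf("duration must be >= 0")
  if (rate == 0 || duration == 0) return(numeric())
  withSeed(seed, {
    # expected count + 6 sd safety margin, then trim
    m <- rate * duration / 1000
    k <- ceiling(m + 6 * sqrt(m) + 10)
    t <- cumsum(stats::rexp(k, rate = rate / 1000))
    while (length(t) && t[length(t)] < duration) {
      t <- c(t, t[length(t)] +
               cumsum(stats::rexp(k, rate = rate / 1000)))
    }
    t[t < duration]
  })
}

#' Random-network noise specification
#'
#' Parameters of the sparse recurrent random network (RN) of inhibitory
#' neurons used as a deterministic noise source: network size, in-degrees
#' and the internal synaptic weight in digital (hardware) units. The
#' defaults are the benchmark values for 5-unit sampling networks (200
#' inhibitory neurons, within-population in-degree 20, 15 excitatory plus 15
#' inhibitory projections onto each sampling neuron, internal weight 10).
#'
#' @param nR number of RN neurons.
#' @param kRN within-population in-degree of each RN neuron.
#' @param kNoise per-type in-degree of each sampling neuron from the RN.
#' @param wRN RN-internal synaptic weight, digital units.
#' @param wProj RN-to-sampling projection weight, digital units. Calibrated
#'   so that the activation function of an RN-driven sampling unit matches
#'   the Poisson-driven one (width s ~ 2.6 vs 2.7 digital units at the
#'   default working point); values above the 4-bit ceiling of 15 stand for
#'   a multapse (parallel synapses on the same connection).
#' @return a list with class \code{"randomNetworkSpec"}.
#' @export
randomNetworkSpec <- function(nR = 200, kRN = 20, kNoise = 15, wRN = 10,
                              wProj = 2 * wRN) {
  stopifnot(nR >= 2, kRN > 0, kNoise >= 0, wRN >= 0, wProj >= 0)
  if (kRN >= nR) stopf("kRN must be < nR (no self-connections possible)")
  if (kNoise > nR) stopf("kNoise cannot exceed the RN size")
  structure(list(nR = as.integer(nR), kRN = as.integer(kRN),
                 kNoise = as.integer(kNoise), wRN = wRN, wProj = wProj),
            class = "randomNetworkSpec")
}

#' Build the recurrent inhibitory random network
#'
#' Constructs the RN wiring: every RN neuron is inhibitory with a
#' suprathreshold leak potential (self-driven activity) and receives exactly
#' \code{kRN} inhibitory inputs from distinct other RN neurons (no
#' self-connections). Each sampling neuron receives exactly \code{kNoise}
#' excitatory and \code{kNoise} inhibitory projections from randomly chosen
#' RN neurons (without replacement per target and type). On the substrate
#' the synapse type is a property of the connection, not of the presynaptic
#' neuron, so RN neurons project through excitatory circuits even though
#' their internal coupling is inhibitory.
#'
#' @param spec a [randomNetworkSpec()].
#' @param samplingIds neuron indices of the sampling neurons the RN feeds.
#' @param offset index of the first RN neuron minus one (RN neurons occupy
#'   \code{offset + 1:nR} in the final network).
#' @param unitScale conductance per digital weight unit, nS.
#' @param delay synaptic delay, ms.
#' @param seed integer seed for the random wiring.
#' @return list with \code{neurons} (data.frame of RN neuron parameters) and
#'   \code{synapses} (data.frame of RN-internal plus RN-to-sampling
#'   synapses).
#' @export
buildRandomNetwork <- function(spec, samplingIds, offset, unitScale = 1,
                               delay = 1, seed = 1L) {
  stopifnot(inherits(spec, "randomNetworkSpec"))
  nR <- spec$nR
  neurons <- rnNeuronParams()[rep(1L, nR), ]
  rownames(neurons) <- NULL
  rnIds <- offset + seq_len(nR)
  withSeed(seed, {
    pre <- unlist(lapply(seq_len(nR), function(i)
      sample(rnIds[-i], spec$kRN)), use.names = FALSE)
    post <- rep(rnIds, each = spec$kRN)
    internal <- data.frame(pre = pre, post = post,
                           weight = spec$wRN * unitScale, kind = "inh",
                           delay = delay, multapse = FALSE,
                           stringsAsFactors = FALSE)
    proj <- do.call(rbind, lapply(samplingIds, function(sid) {
      data.frame(pre = c(sample(rnIds, spec$kNoise),
                         sample(rnIds, spec$kNoise)),
                 post = sid, weight = spec$wProj * unitScale,
                 kind = rep(c("exc", "inh"), each = spec$kNoise),
                 delay = delay, multapse = FALSE, stringsAsFactors = FALSE)
    }))
    list(neurons = neurons, synapses = rbind(internal, proj))
  })
}

#' Rates and pairwise correlations of spike trains
#'
#' Quantifies a noise backend: per-source firing rates and Pearson
#' correlation coefficients of spike counts in time bins, for all source
#' pairs. Shared-input correlations of random-network projections show up
#' here as positive mean pairwise correlation; independent Poisson sources
#' scatter around zero.
#'
#' @param trains list of spike time vectors (or [SpikeTrain-class]s).
#' @param bin bin width, ms.
#' @param duration observation time, ms; defaults to the latest spike.
#' @return list with \code{rates} (Hz) and \code{correlations} (data.frame
#'   with columns i, j, rho).
#' @export
noiseStatistics <- function(trains, bin, duration = NULL) {
  tl <- lapply(trains, function(x)
    if (is(x, "SpikeTrain")) x@times else as.numeric(x))
  if (is.null(duration))
    duration <- max(c(0, unlist(tl, use.names = FALSE)))
  if (duration <= 0 || bin <= 0 || duration < bin)
    stopf("need a positive duration spanning at least one bin")
  breaks <- seq(0, duration, by = bin)
  if (length(breaks) < 2L) stopf("need at least one full bin")
  counts <- vapply(tl, function(t) {
    kept <- t[t >= 0 & t < breaks[length(breaks)]]
    tabulate(findInterval(kept, breaks), nbins = length(breaks) - 1L)
  }, numeric(length(breaks) - 1L))
  rates <- 1000 * lengths(tl) / duration
  k <- length(tl)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  rho <- apply(pairs, 1L, function(ij)
    suppressWarnings(stats::cor(counts[, ij[1]], counts[, ij[2]])))
  list(rates = rates,
       correlations = data.frame(i = pairs[, 1], j = pairs[, 2], rho = rho))
}
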