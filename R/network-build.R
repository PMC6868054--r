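#' Build a spiking sampling network
#'
#' Constructs a [SamplingNetwork-class] of \code{nUnits} sampling units.
#' Each unit is a pair of neurons: a sampling neuron encoding the binary RV
#' and a regularly firing suprathreshold-leak bias neuron that implements
#' the unit's bias through an excitatory/inhibitory synapse pair whose
#' digital weight is plastic. Couplings between sampling neurons are
#' likewise paired plastic synapses. Stochasticity comes from one of two
#' backends: private Poisson input per sampling neuron ("poisson") or a
#' recurrent inhibitory random network instantiated alongside the sampling
#' units ("rn").
#'
#' The returned object carries continuous shadow weights (all zero
#' initially); [realizeNetwork()] turns them into a concrete
#' [NetworkDefinition-class], applying 4-bit discretization and substrate
#' variability.
#'
#' @param nUnits number of sampling units.
#' @param noise noise backend, \code{"poisson"} or \code{"rn"}.
#' @param noiseRate Poisson rate per synapse type, Hz.
#' @param noiseWeight Poisson synapse weight, nS.
#' @param rnSpec a [randomNetworkSpec()] (used when \code{noise = "rn"}).
#' @param sharedBias if \code{TRUE}, one bias neuron serves all sampling
#'   units (through distinct synapses); otherwise one bias neuron per unit.
#' @param unitScale conductance per digital weight unit, nS. The default
#'   places the logistic activation width at roughly 2-3 digital units, so
#'   the 4-bit range \code{[-15, 15]} spans biases of a few units of
#'   abstract magnitude.
#' @param variability a [VariabilityModel-class].
#' @param substrateSeed integer seed fixing the persistent fixed-pattern
#'   perturbation (and the RN wiring).
#' @param delay synaptic delay, ms.
#' @param samplingParams,biasParams one-row neuron parameter data.frames
#'   (see [neuronParameters()]) for the sampling and bias neurons.
#' @param layout internal; unit group tags for hierarchical networks.
#' @param pairs internal; restricted coupling pair matrix.
#' @return a [SamplingNetwork-class].
#' @export
#' @examples
#' ssn <- buildSamplingNetwork(5, substrateSeed = 1)
#' ssn
buildSamplingNetwork <- function(nUnits, noise = c("poisson", "rn"),
                                 noiseRate = 300, noiseWeight = 30,
                                 rnSpec = randomNetworkSpec(),
                                 sharedBias = FALSE, unitScale = 2.8,
                                 variability = variabilityModel(),
                                 substrateSeed = 1L, delay = 1,
                                 samplingParams = samplingNeuronParams(),
                                 biasParams = biasNeuronParams(),
                                 layout = list(type = "flat"),
                                 pairs = NULL) {
  noise <- match.arg(noise)
  n <- as.integer(nUnits)
  stopifnot(n >= 1)
  nb <- if (sharedBias) 1L else n
  sampling <- samplingParams[rep(1L, n), ]
  bias <- biasParams[rep(1L, nb), ]
  neurons <- rbind(sampling, bias)
  samplingIds <- seq_len(n)
  biasIds <- if (sharedBias) rep(n + 1L, n) else n + seq_len(n)

  synapses <- emptySynapses()
  ext <- emptyExtSynapses()
  noiseCfg <- list(type = noise, rate = noiseRate, weight = noiseWeight,
                   ports = character())
  if (noise == "poisson") {
    pe <- sprintf("noise_e_%d", samplingIds)
    pi_ <- sprintf("noise_i_%d", samplingIds)
    ext <- data.frame(port = c(pe, pi_), post = rep(samplingIds, 2),
                      weight = noiseWeight,
                      kind = rep(c("exc", "inh"), each = n), delay = delay,
                      stringsAsFactors = FALSE)
    noiseCfg$ports <- c(pe, pi_)
  } else {
    rn <- buildRandomNetwork(rnSpec, samplingIds, offset = n + nb,
                             unitScale = unitScale, delay = delay,
                             seed = childSeed(substrateSeed, 17L))
    neurons <- rbind(neurons, rn$neurons)
    synapses <- rbind(synapses, rn$synapses)
    noiseCfg$rnSpec <- rnSpec
    noiseCfg$rnIds <- n + nb + seq_len(rnSpec$nR)
  }
  net <- networkDefinition(neurons, synapses, ext)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    colnames(pairs) <- NULL
  }
  new("SamplingNetwork", net = net, samplingIds = samplingIds,
      biasIds = as.integer(biasIds),
      pairs = matrix(as.integer(pairs), ncol = 2),
      biasDigital = numeric(n), couplingDigital = matrix(0, n, n),
      unitScale = unitScale, noise = noiseCfg, fits = list(),
      kappa = numeric(0),
      variability = variability, substrateSeed = as.integer(substrateSeed),
      layout = layout)
}

#' Build a hierarchical sampling network for image data
#'
#' Three-layer sampling network (visible, hidden, label) with plastic
#' couplings restricted to visible-hidden and hidden-label pairs, the
#' architecture used for classification, pattern completion and guided
#' dreaming on 12 x 12 binary images. Bias neurons are shared by default to
#' mirror the resource-saving layout of large substrate networks.
#'
#' @param nVisible,nHidden,nLabels layer sizes; \code{nVisible} must match
#'   the image length (144).
#' @param ... passed to [buildSamplingNetwork()].
#' @param sharedBias see [buildSamplingNetwork()]; default \code{TRUE}.
#' @return a [SamplingNetwork-class] with a hierarchical layout.
#' @export
buildHierarchicalNetwork <- function(nVisible = 144, nHidden = 60,
                                     nLabels = 3, sharedBias = TRUE, ...) {
  v <- seq_len(nVisible)
  h <- nVisible + seq_len(nHidden)
  l <- nVisible + nHidden + seq_len(nLabels)
  pairs <- rbind(cbind(rep(v, each = nHidden), rep(h, nVisible)),
                 cbind(rep(h, each = nLabels), rep(l, nHidden)))
  layout <- list(type = "hierarchical", visible = v, hidden = h, label = l)
  buildSamplingNetwork(nVisible + nHidden + nLabels, sharedBias = sharedBias,
                       layout = layout, pairs = pairs, ...)
}

#' Realize a sampling network on its substrate
#'
#' Turns the abstract sampling network (continuous shadow weights) into a
#' concrete [NetworkDefinition-class]: digital weights are discretized to
#' the paired 4-bit representation (sign routes to the excitatory or
#' inhibitory synapse of each pair), converted to conductances through the
#' unit scale, and perturbed by the substrate's fixed pattern
#' (substrate seed) and, when a trial seed is given, by a fresh
#' trial-to-trial rewrite.
#'
#' @param ssn a [SamplingNetwork-class].
#' @param trialSeed integer seed of this experiment run's analog rewrite;
#'   \code{NULL} skips the trial perturbation.
#' @param discretize apply 4-bit discretization (\code{FALSE} keeps
#'   continuous weights, clipped to the representable range \code{[-15,15]}).
#' @param variability apply the substrate variability model (\code{FALSE}
#'   gives an ideal substrate).
#' @param disablePreUnits unit indices whose outgoing plastic couplings are
#'   turned off (used to cut top-down synapses during the wake phase).
#' @return a [NetworkDefinition-class] ready for [simulateNetwork()].
#' @export
realizeNetwork <- function(ssn, trialSeed = NULL, discretize = TRUE,
                           variability = TRUE,
                           disablePreUnits = integer()) {
  stopifnot(is(ssn, "SamplingNetwork"))
  n <- nUnits(ssn)
  clip <- function(w) pmin(pmax(w, -15), 15)
  dig <- if (discretize) {
    list(b = discretizeSigned(ssn@biasDigital),
         W = matrix(discretizeSigned(ssn@couplingDigital), n, n))
  } else {
    list(b = clip(ssn@biasDigital), W = clip(ssn@couplingDigital))
  }

  P <- ssn@pairs
  preU <- c(P[, 1], P[, 2])
  postU <- c(P[, 2], P[, 1])
  wdir <- c(dig$W[P], dig$W[P])
  # paired synapses: both members always present pre-perturbation so the
  # fixed-pattern factor of a circuit does not depend on current weights
  coup <- if (length(wdir)) data.frame(
    pre = rep(ssn@samplingIds[preU], 2),
    post = rep(ssn@samplingIds[postU], 2),
    weight = c(pmax(wdir, 0), pmax(-wdir, 0)) * ssn@unitScale,
    kind = rep(c("exc", "inh"), each = length(wdir)),
    delay = 1, multapse = FALSE, stringsAsFactors = FALSE)
  else emptySynapses()
  biasRows <- data.frame(
    pre = rep(ssn@biasIds, 2), post = rep(ssn@samplingIds, 2),
    weight = c(pmax(dig$b, 0), pmax(-dig$b, 0)) * ssn@unitScale,
    kind = rep(c("exc", "inh"), each = n),
    delay = 1, multapse = FALSE, stringsAsFactors = FALSE)

  net <- ssn@net
  nStatic <- nrow(net@synapses)
  net@synapses <- rbind(net@synapses, coup, biasRows)
  if (variability) {
    net <- applyFixedPattern(net, ssn@variability, ssn@substrateSeed)
    if (!is.null(trialSeed))
      net <- trialRewrite(net, ssn@variability, as.integer(trialSeed))
  }
  if (length(disablePreUnits)) {
    off <- nStatic + which(preU %in% disablePreUnits)
    net@synapses$weight[c(off, off + length(wdir))] <- 0
  }
  net@synapses <- net@synapses[net@synapses$weight > 0, , drop = FALSE]
  rownames(net@synapses) <- NULL
  validObject(net)
  net
}

#' Digital weight assignment
#'
#' \code{setDigitalWeights} replaces the continuous shadow weights of a
#' sampling network (couplings must respect the network's pair mask and be
#' symmetric).
#'
#' @param ssn a [SamplingNetwork-class].
#' @param bias numeric length-n bias weights, digital units.
#' @param coupling numeric n x n symmetric coupling matrix, digital units.
#' @return the updated [SamplingNetwork-class].
#' @export
setDigitalWeights <- function(ssn, bias = NULL, coupling = NULL) {
  if (!is.null(bias)) ssn@biasDigital <- as.numeric(bias)
  if (!is.null(coupling)) {
    mask <- matrix(FALSE, nUnits(ssn), nUnits(ssn))
    mask[ssn@pairs] <- TRUE
    mask <- mask | t(mask)
    if (any(coupling[!mask] != 0))
      stopf("coupling weights outside the network's pair mask must be zero")
    ssn@couplingDigital <- (coupling + t(coupling)) / 2
  }
  validObject(ssn)
  ssn
}

#' Noise input trains for a sampling network
#'
#' Generates the external input spike trains of the network's noise backend
#' for one run: independent Poisson trains per port for the "poisson"
#' backend, nothing for the self-contained "rn" backend.
#'
#' @param ssn a [SamplingNetwork-class].
#' @param duration run length, ms.
#' @param seed integer seed; each port gets an independent child stream.
#' @return named list of spike time vectors, one per noise port.
#' @export
noiseInputs <- function(ssn, duration, seed) {
  if (ssn@noise$type != "poisson") return(list())
  ports <- ssn@noise$ports
  tr <- lapply(seq_along(ports), function(k)
    poissonTrain(ssn@noise$rate, duration, childSeed(seed, k)))
  names(tr) <- ports
  tr
}

# Add clamp input ports (5-fold multapse, excitatory and inhibitory) for the
# given neurons to a realized network definition. Clamp inputs come from the
# host, so they are attached after substrate perturbation.
addClampPorts <- function(net, neuronIds, weight, multapse = 5L,
                          delay = 1) {
  rows <- expand.grid(m = seq_len(multapse), kind = c("exc", "inh"),
                      post = neuronIds, stringsAsFactors = FALSE)
  ext <- data.frame(
    port = sprintf("clamp_%s_%d_%d", substr(rows$kind, 1, 1), rows$post,
                   rows$m),
    post = rows$post, weight = weight, kind = rows$kind, delay = delay,
    stringsAsFactors = FALSE)
  net@extSynapses <- rbind(net@extSynapses, ext)
  net@ports <- unique(c(net@ports, ext$port))
  validObject(net)
  net
}

# One simulation run of a sampling network: realize, wire noise and clamp
# inputs, simulate. `clampPattern` is a named 0/1 vector over unit indices.
# Returns list(spikes, net, inputs).
ssnRun <- function(ssn, duration, dt = 0.1, trialSeed = NULL, noiseSeed = 1L,
                   discretize = TRUE, variability = TRUE,
                   clampPattern = NULL, clampWeight = NULL,
                   disablePreUnits = integer(), record = integer()) {
  net <- realizeNetwork(ssn, trialSeed = trialSeed, discretize = discretize,
                        variability = variability,
                        disablePreUnits = disablePreUnits)
  inputs <- noiseInputs(ssn, duration, noiseSeed)
  if (!is.null(clampPattern) && length(clampPattern)) {
    units <- as.integer(names(clampPattern))
    nrnIds <- ssn@samplingIds[units]
    if (is.null(clampWeight)) clampWeight <- 15 * ssn@unitScale
    net <- addClampPorts(net, nrnIds, clampWeight)
    inputs <- c(inputs,
                clampPortInputs(nrnIds, as.integer(clampPattern), duration))
  }
  sim <- simulateNetwork(net, inputs, duration = duration, dt = dt,
                         record = record)
  list(spikes = sim$spikes, traces = sim$traces, net = net, inputs = inputs)
}
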