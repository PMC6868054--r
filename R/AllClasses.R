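#' @import methods
NULL

#' Boltzmann target distribution over binary random variables
#'
#' Defines the target distribution \deqn{p^*(z) = \frac{1}{Z}
#' \exp(\tfrac{1}{2} z^T W z + z^T b)} over states \eqn{z \in \{0,1\}^n},
#' with a symmetric, zero-diagonal coupling matrix \eqn{W} and bias vector
#' \eqn{b}, both dimensionless. The partition sum \eqn{Z} is computed on
#' demand, never stored.
#'
#' @slot W symmetric numeric matrix with zero diagonal.
#' @slot b numeric bias vector, one entry per random variable.
#' @seealso [boltzmannTarget()], [targetJoint()], [randomTarget()]
#' @export
setClass("BoltzmannTarget", representation(W = "matrix", b = "numeric"))

setValidity("BoltzmannTarget", function(object) {
  W <- object@W; b <- object@b
  n <- length(b)
  if (n < 1L) return("need at least one random variable")
  if (!is.numeric(W) || nrow(W) != n || ncol(W) != n)
    return("W must be a numeric n x n matrix matching length(b)")
  if (any(!is.finite(W)) || any(!is.finite(b)))
    return("W and b must be finite")
  if (max(abs(W - t(W))) > 1e-10) return("W must be symmetric")
  if (max(abs(diag(W))) > 1e-12) return("W must have a zero diagonal")
  TRUE
})

#' Probability table over binary state vectors
#'
#' Explicit probability vector over all \eqn{2^n} states of \eqn{n} binary
#' random variables. States are ordered by their index
#' \eqn{1 + \sum_k z_k 2^{k-1}}, i.e. unit 1 is the fastest-varying bit.
#'
#' @slot n integer, number of binary random variables.
#' @slot p numeric vector of length \code{2^n}; non-negative, sums to one.
#' @seealso [probabilityTable()], [stateMatrix()], [dkl()]
#' @export
setClass("ProbabilityTable", representation(n = "integer", p = "numeric"))

setValidity("ProbabilityTable", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  if (length(object@p) != 2^object@n)
    return("p must have length 2^n")
  if (any(object@p < -1e-12)) return("probabilities must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-9) return("probabilities must sum to 1")
  TRUE
})

#' Timestamped spike events
#'
#' A flat, time-sorted record of spikes \code{(time, source id)} over an
#' observation window \code{[0, duration)}. Times are in biological-time
#' milliseconds; ids are 1-based neuron (or source) indices.
#'
#' @slot times numeric, non-decreasing spike times in ms.
#' @slot ids integer source ids, parallel to \code{times}.
#' @slot duration numeric scalar, length of the observation window in ms.
#' @seealso [spikeTrain()], [extractStates()]
#' @export
setClass("SpikeTrain",
         representation(times = "numeric", ids = "integer",
                        duration = "numeric"))

setValidity("SpikeTrain", function(object) {
  if (length(object@times) != length(object@ids))
    return("times and ids must have equal length")
  if (length(object@times) && min(object@times) < 0)
    return("spike times must be >= 0")
  if (is.unsorted(object@times)) return("spike times must be non-decreasing")
  if (length(object@duration) != 1L || object@duration < 0)
    return("duration must be a non-negative scalar")
  TRUE
})

#' Piecewise-constant binary network state
#'
#' The refractory-based state vector \eqn{z(t)}: unit \eqn{k} is in the
#' on-state (\eqn{z_k = 1}) exactly on the union of its refractory windows
#' \eqn{[t_{sp}, t_{sp} + \tau_{ref})}. Interval \code{i} spans
#' \code{[breakpoints[i], breakpoints[i+1])} and holds state
#' \code{states[i, ]}; the intervals tile the observation window.
#'
#' @slot breakpoints numeric vector of length \code{nrow(states) + 1},
#'   strictly increasing.
#' @slot states integer matrix (intervals x units) of 0/1 values.
#' @seealso [extractStates()], [empiricalJoint()]
#' @export
setClass("StateSequence",
         representation(breakpoints = "numeric", states = "matrix"))

setValidity("StateSequence", function(object) {
  m <- nrow(object@states)
  if (length(object@breakpoints) != m + 1L)
    return("breakpoints must have length nrow(states) + 1")
  if (m > 0 && any(diff(object@breakpoints) <= 0))
    return("breakpoints must be strictly increasing")
  if (m > 0 && !all(object@states %in% c(0L, 1L)))
    return("states must be 0/1")
  TRUE
})

#' Network definition: neurons, synapses and external input ports
#'
#' A complete, unit-explicit description of an LIF network. \code{neurons}
#' holds one row per neuron with its parameters (mV, ms, nF) and a role tag
#' (\code{sampling}, \code{bias}, \code{random}, \code{visible},
#' \code{hidden}, \code{label}). \code{synapses} holds recurrent
#' connections; \code{extSynapses} attaches named external input ports to
#' target neurons. Synaptic weights are conductances in nS (always >= 0; the
#' \code{kind} column selects the excitatory or inhibitory reversal
#' potential).
#'
#' @slot neurons data.frame of per-neuron parameters and roles.
#' @slot synapses data.frame with columns pre, post, weight, kind, delay,
#'   multapse.
#' @slot extSynapses data.frame with columns port, post, weight, kind, delay.
#' @slot ports character vector of declared external input port names.
#' @seealso [networkDefinition()], [simulateNetwork()]
#' @export
setClass("NetworkDefinition",
         representation(neurons = "data.frame", synapses = "data.frame",
                        extSynapses = "data.frame", ports = "character"))

setValidity("NetworkDefinition", function(object) {
  nrn <- object@neurons
  need <- c("role", "V_reset", "E_leak", "V_thresh", "E_inh", "E_exc",
            "tau_ref", "tau_mem", "C_mem", "tau_syn_exc", "tau_syn_inh")
  if (!all(need %in% names(nrn)))
    return(paste("neurons must have columns:", paste(need, collapse = ", ")))
  n <- nrow(nrn)
  if (n < 1L) return("need at least one neuron")
  tc <- as.matrix(nrn[, c("tau_ref", "tau_mem", "tau_syn_exc",
                          "tau_syn_inh")])
  if (any(!is.finite(tc)) || any(tc <= 0))
    return("all time constants must be finite and > 0")
  if (any(nrn$C_mem <= 0)) return("C_mem must be > 0")
  if (any(nrn$E_inh >= nrn$V_thresh) || any(nrn$V_thresh >= nrn$E_exc))
    return("need E_inh < V_thresh < E_exc for every neuron")
  syn <- object@synapses
  if (nrow(syn)) {
    if (any(syn$pre < 1L | syn$pre > n | syn$post < 1L | syn$post > n))
      return("synapse endpoints must reference existing neurons")
    if (any(syn$weight < 0)) return("synaptic weights must be >= 0")
    if (any(syn$delay < 0)) return("synaptic delays must be >= 0")
    if (!all(syn$kind %in% c("exc", "inh")))
      return("synapse kind must be 'exc' or 'inh'")
    plain <- !syn$multapse
    if (anyDuplicated(syn[plain, c("pre", "post", "kind")]))
      return("duplicate (pre, post, kind) synapses must be marked multapse")
  }
  ext <- object@extSynapses
  if (nrow(ext)) {
    if (any(ext$post < 1L | ext$post > n))
      return("external synapse targets must reference existing neurons")
    if (any(ext$weight < 0) || any(ext$delay < 0))
      return("external synapse weights and delays must be >= 0")
    if (!all(ext$kind %in% c("exc", "inh")))
      return("external synapse kind must be 'exc' or 'inh'")
    if (!all(ext$port %in% object@ports))
      return("external synapses reference undeclared ports")
  }
  TRUE
})

#' Logistic activation-function fit of a sampling unit
#'
#' Parameters of the logistic activation function
#' \deqn{\langle\nu\rangle = \nu_0 / \{1 + \exp[-(w_b - w_{b0})/s]\}}
#' relating a sampling neuron's mean firing rate to its bias weight
#' \eqn{w_b} (digital units). The fit provides the translation between
#' abstract Boltzmann parameters and substrate weights: the midpoint
#' \eqn{w_{b0}} is the 50%-activity point and the width \eqn{s} is the
#' digital-weight equivalent of one unit of abstract bias.
#'
#' @slot nu0 saturation rate in Hz.
#' @slot wb0 midpoint in bias-weight (digital) units.
#' @slot s width in bias-weight (digital) units.
#' @seealso [fitActivation()], [measureActivation()], [translateParameters()]
#' @export
setClass("ActivationFit",
         representation(nu0 = "numeric", wb0 = "numeric", s = "numeric"))

setValidity("ActivationFit", function(object) {
  if (object@nu0 <= 0) return("nu0 must be > 0")
  if (object@s <= 0) return("s must be > 0")
  TRUE
})

#' Substrate variability model
#'
#' Statistical stand-in for an analog substrate's imperfections: persistent
#' fixed-pattern (circuit-to-circuit) variability and trial-to-trial spread
#' from rewriting analog parameter storage. All spreads are coefficients of
#' variation of multiplicative lognormal factors with mean one
#' (multiplicative noise keeps conductances and time constants positive).
#' The fixed pattern is drawn once per substrate seed and persists; trial
#' factors are redrawn per experiment run. Digital (4-bit) weights are never
#' touched by either.
#'
#' @slot cvWeightFixed fixed-pattern CV of synaptic conductance scale.
#' @slot cvTauSynFixed fixed-pattern CV of per-neuron synaptic time
#'   constants.
#' @slot cvWeightTrial trial-to-trial CV of synaptic conductance scale.
#' @seealso [variabilityModel()], [applyFixedPattern()], [trialRewrite()]
#' @export
setClass("VariabilityModel",
         representation(cvWeightFixed = "numeric", cvTauSynFixed = "numeric",
                        cvWeightTrial = "numeric"))

setValidity("VariabilityModel", function(object) {
  cv <- c(object@cvWeightFixed, object@cvTauSynFixed, object@cvWeightTrial)
  if (length(cv) != 3L || any(!is.finite(cv)) || any(cv < 0))
    return("all CVs must be finite and >= 0")
  TRUE
})

#' Binary image dataset
#'
#' Flat binary images (one row per image, 144 pixels = 12 x 12) with class
#' labels and train/test split tags, as produced by
#' [makeSyntheticDataset()] or by reducing and binarizing user-supplied
#' grayscale images.
#'
#' @slot images integer matrix (images x 144) of 0/1 pixels.
#' @slot labels integer class labels in 1..nClasses.
#' @slot split character vector of "train"/"test" tags.
#' @slot nClasses integer number of classes.
#' @slot prototypes integer matrix (nClasses x 144) of class prototypes
#'   (zero rows when unknown).
#' @export
setClass("ImageDataset",
         representation(images = "matrix", labels = "integer",
                        split = "character", nClasses = "integer",
                        prototypes = "matrix"))

setValidity("ImageDataset", function(object) {
  if (ncol(object@images) != 144L) return("images must have 144 pixels")
  if (!all(object@images %in% c(0L, 1L))) return("pixels must be 0/1")
  if (length(object@labels) != nrow(object@images))
    return("one label per image required")
  if (any(object@labels < 1L | object@labels > object@nClasses))
    return("labels must lie in 1..nClasses")
  if (length(object@split) != nrow(object@images))
    return("one split tag per image required")
  if (!all(object@split %in% c("train", "test")))
    return("split tags must be 'train' or 'test'")
  TRUE
})

#' Spiking sampling network
#'
#' A sampling network bound to an analog-like substrate: the static network
#' scaffold (sampling neurons, bias neurons, noise wiring), the plastic
#' digital weights (continuous shadow values; discretized to 4 bits when the
#' network is realized), the digital-to-conductance unit scale, the noise
#' backend, per-unit activation fits, the variability model and the
#' substrate seed that fixes the persistent fixed-pattern perturbation.
#'
#' Plastic connections are paired excitatory/inhibitory synapses; the sign
#' of a digital weight selects which member of the pair carries the
#' conductance. Use [realizeNetwork()] to obtain a concrete
#' [NetworkDefinition-class] for simulation.
#'
#' @slot net base [NetworkDefinition-class] with static synapses only.
#' @slot samplingIds,biasIds neuron indices of the sampling neurons and of
#'   each unit's bias neuron (recycled when bias neurons are shared).
#' @slot pairs integer 2-column matrix of unit pairs (i < j) that carry
#'   plastic couplings.
#' @slot biasDigital numeric shadow bias weights (digital units, signed).
#' @slot couplingDigital numeric shadow coupling matrix (digital units,
#'   signed, symmetric, zero outside \code{pairs}).
#' @slot unitScale conductance per digital weight unit, nS.
#' @slot noise list describing the noise backend (type "poisson" or "rn",
#'   rates, weights, port names).
#' @slot fits list of per-unit [ActivationFit-class] (empty before
#'   calibration).
#' @slot kappa numeric; empirically calibrated coupling conversion factor
#'   (length 0 before calibration; see [couplingScale()]).
#' @slot variability [VariabilityModel-class].
#' @slot substrateSeed integer seed of the persistent fixed pattern.
#' @slot layout list tagging unit groups (visible/hidden/label) for
#'   hierarchical networks; \code{list(type = "flat")} otherwise.
#' @seealso [buildSamplingNetwork()], [buildHierarchicalNetwork()],
#'   [realizeNetwork()], [trainToTarget()]
#' @export
setClass("SamplingNetwork",
         representation(net = "NetworkDefinition", samplingIds = "integer",
                        biasIds = "integer", pairs = "matrix",
                        biasDigital = "numeric", couplingDigital = "matrix",
                        unitScale = "numeric", noise = "list", fits = "list",
                        kappa = "numeric",
                        variability = "VariabilityModel",
                        substrateSeed = "integer", layout = "list"))

setValidity("SamplingNetwork", function(object) {
  n <- length(object@samplingIds)
  if (length(object@biasIds) != n)
    return("need one bias neuron id per sampling unit")
  if (length(object@biasDigital) != n)
    return("biasDigital must have one entry per unit")
  if (!identical(dim(object@couplingDigital), c(n, n)))
    return("couplingDigital must be n x n")
  if (max(abs(object@couplingDigital - t(object@couplingDigital))) > 1e-9)
    return("couplingDigital must be symmetric")
  if (length(object@unitScale) != 1L || object@unitScale <= 0)
    return("unitScale must be a positive scalar")
  TRUE
})

#' Result of an experiment protocol
#'
#' Container for the reproducible experiment pipelines: a protocol tag, the
#' evaluation grid with its time-resolved metric, a scalar summary, and the
#' seeds and configuration needed to reproduce the run exactly.
#'
#' @slot protocol character tag ("sampling", "inference", "classify",
#'   "completion", "dream").
#' @slot times numeric evaluation grid (ms).
#' @slot metric numeric metric values on the grid (DKL in nats, MSE, or
#'   error ratio, depending on the protocol).
#' @slot summary numeric named scalar summary.
#' @slot seeds integer named seed vector.
#' @slot config list, configuration snapshot.
#' @slot detail list, protocol-specific extras (predicted labels, snapshots,
#'   flags).
#' @export
setClass("ExperimentResult",
         representation(protocol = "character", times = "numeric",
                        metric = "numeric", summary = "numeric",
                        seeds = "integer", config = "list", detail = "list"))

setValidity("ExperimentResult", function(object) {
  if (length(object@metric) != length(object@times))
    return("metric must be aligned to the evaluation grid")
  if (any(!is.finite(object@metric))) return("all metric values must be finite")
  TRUE
})
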