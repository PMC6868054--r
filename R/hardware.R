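#' 4-bit paired-synapse weight discretization
#'
#' Digital synaptic weights are stored with 4-bit resolution per synapse,
#' and every logical connection is a pair of one excitatory and one
#' inhibitory synapse of which at most one is nonzero. \code{discretizeWeight}
#' maps continuous weights to that representation: the magnitude (in digital
#' units, i.e. \code{w / unitScale}) is rounded half-away-from-zero to the
#' nearest integer and clipped to \code{[0, 15]}; the sign routes the value
#' to the excitatory (positive) or inhibitory (negative) slot. Deterministic.
#'
#' \code{discretizeSigned} is the signed integer convenience form in
#' \code{[-15, 15]} used by the training loop.
#'
#' @param w numeric weight(s); digital units when \code{unitScale = 1}.
#' @param unitScale conductance (or weight) per digital unit (> 0).
#' @return \code{discretizeWeight}: integer matrix with columns \code{exc}
#'   and \code{inh}; \code{discretizeSigned}: signed integer vector.
#' @export
#' @examples
#' discretizeWeight(c(7.4, -3.6, 22))
discretizeWeight <- function(w, unitScale = 1) {
  stopifnot(unitScale > 0)
  if (any(!is.finite(w))) stopf("weights must be finite")
  d <- discretizeSigned(w, unitScale)
  cbind(exc = pmax(d, 0L), inh = pmax(-d, 0L))
}

#' @rdname discretizeWeight
#' @export
discretizeSigned <- function(w, unitScale = 1) {
  if (any(!is.finite(w))) stopf("weights must be finite")
  mag <- pmin(floor(abs(w) / unitScale + 0.5), 15)
  as.integer(sign(w) * mag)
}

#' @param cvWeightFixed fixed-pattern coefficient of variation of synaptic
#'   conductance scale (default 20\%).
#' @param cvTauSynFixed fixed-pattern CV of per-neuron synaptic time
#'   constants (default 10\%).
#' @param cvWeightTrial trial-to-trial CV of synaptic conductance scale
#'   (default 1\%, calibrated so that the trial-to-trial spread of unit
#'   activation functions stays at the sub-Hz order observed on analog
#'   substrates).
#' @return a [VariabilityModel-class].
#' @rdname VariabilityModel-class
#' @export
#' @examples
#' variabilityModel()           # substrate-like defaults
#' variabilityModel(0, 0, 0)    # ideal substrate
variabilityModel <- function(cvWeightFixed = 0.2, cvTauSynFixed = 0.1,
                             cvWeightTrial = 0.01) {
  new("VariabilityModel", cvWeightFixed = cvWeightFixed,
      cvTauSynFixed = cvTauSynFixed, cvWeightTrial = cvWeightTrial)
}

#' Apply substrate variability to a network
#'
#' \code{applyFixedPattern} imposes the persistent circuit-to-circuit
#' mismatch of an analog substrate: every synaptic conductance (recurrent
#' and external) is multiplied by an independent lognormal factor with CV
#' \code{cvWeightFixed}, and every neuron's synaptic time constants by
#' factors with CV \code{cvTauSynFixed}. The same seed always reproduces the
#' same perturbation — the seed is the substrate's identity. Factors are
#' drawn in a fixed order (neurons, then recurrent synapses, then external
#' synapses), so networks with identical topology receive identical factors.
#'
#' \code{trialRewrite} adds the smaller, per-run perturbation from rewriting
#' analog parameter storage: a fresh lognormal factor with CV
#' \code{cvWeightTrial} per synaptic conductance. Digital weights are not
#' part of the network realization touched here — they live upstream and
#' are bit-identical across trials.
#'
#' @param net a [NetworkDefinition-class].
#' @param model a [VariabilityModel-class].
#' @param seed substrate seed (fixed pattern) or trial seed (rewrite).
#' @return perturbed [NetworkDefinition-class].
#' @export
#' @examples
#' net <- networkDefinition(samplingNeuronParams())
#' identical(applyFixedPattern(net, variabilityModel(), seed = 3),
#'           applyFixedPattern(net, variabilityModel(), seed = 3))
applyFixedPattern <- function(net, model, seed) {
  stopifnot(is(net, "NetworkDefinition"), is(model, "VariabilityModel"))
  withSeed(seed, {
    n <- nrow(net@neurons)
    fe <- lognormFactors(n, model@cvTauSynFixed)
    fi <- lognormFactors(n, model@cvTauSynFixed)
    fw <- lognormFactors(nrow(net@synapses), model@cvWeightFixed)
    fx <- lognormFactors(nrow(net@extSynapses), model@cvWeightFixed)
    net@neurons$tau_syn_exc <- net@neurons$tau_syn_exc * fe
    net@neurons$tau_syn_inh <- net@neurons$tau_syn_inh * fi
    if (nrow(net@synapses)) net@synapses$weight <- net@synapses$weight * fw
    if (nrow(net@extSynapses))
      net@extSynapses$weight <- net@extSynapses$weight * fx
    validObject(net)
    net
  })
}

#' @rdname applyFixedPattern
#' @export
trialRewrite <- function(net, model, seed) {
  stopifnot(is(net, "NetworkDefinition"), is(model, "VariabilityModel"))
  withSeed(seed, {
    fw <- lognormFactors(nrow(net@synapses), model@cvWeightTrial)
    fx <- lognormFactors(nrow(net@extSynapses), model@cvWeightTrial)
    if (nrow(net@synapses)) net@synapses$weight <- net@synapses$weight * fw
    if (nrow(net@extSynapses))
      net@extSynapses$weight <- net@extSynapses$weight * fx
    validObject(net)
    net
  })
}
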