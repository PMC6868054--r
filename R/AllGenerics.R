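#' @rdname accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("spikeIds", function(x) standardGeneric("spikeIds"))

#' @rdname accessors
#' @export
setGeneric("targetWeights", function(x) standardGeneric("targetWeights"))

#' @rdname accessors
#' @export
setGeneric("targetBiases", function(x) standardGeneric("targetBiases"))

#' @rdname accessors
#' @export
setGeneric("digitalWeights", function(x) standardGeneric("digitalWeights"))

#' @rdname accessors
#' @export
setGeneric("activationFits", function(x) standardGeneric("activationFits"))

#' Accessors for spikesampler classes
#'
#' Small read-only accessors: \code{nUnits} gives the number of binary
#' random variables / sampling units; \code{probs} the probability vector of
#' a [ProbabilityTable-class]; \code{spikeTimes}/\code{spikeIds} the event
#' columns of a [SpikeTrain-class]; \code{targetWeights}/\code{targetBiases}
#' the parameters of a [BoltzmannTarget-class]; \code{digitalWeights} the
#' continuous shadow weights of a [SamplingNetwork-class] (a list with
#' elements \code{bias} and \code{coupling}); \code{activationFits} its
#' per-unit calibration fits.
#'
#' @param x an object of the matching class.
#' @return see Description.
#' @name accessors
#' @examples
#' tgt <- randomTarget(3, seed = 1)
#' nUnits(tgt)
#' targetBiases(tgt)
NULL

#' @rdname accessors
#' @export
setMethod("nUnits", "BoltzmannTarget", function(x) length(x@b))

#' @rdname accessors
#' @export
setMethod("nUnits", "ProbabilityTable", function(x) as.integer(x@n))

#' @rdname accessors
#' @export
setMethod("nUnits", "StateSequence", function(x) ncol(x@states))

#' @rdname accessors
#' @export
setMethod("nUnits", "SamplingNetwork", function(x) length(x@samplingIds))

#' @rdname accessors
#' @export
setMethod("probs", "ProbabilityTable", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("spikeIds", "SpikeTrain", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("targetWeights", "BoltzmannTarget", function(x) x@W)

#' @rdname accessors
#' @export
setMethod("targetBiases", "BoltzmannTarget", function(x) x@b)

#' @rdname accessors
#' @export
setMethod("digitalWeights", "SamplingNetwork",
          function(x) list(bias = x@biasDigital, coupling = x@couplingDigital))

#' @rdname accessors
#' @export
setMethod("activationFits", "SamplingNetwork", function(x) x@fits)

setMethod("show", "BoltzmannTarget", function(object) {
  cat(sprintf("BoltzmannTarget over %d binary RVs\n", length(object@b)))
  cat(sprintf("  |b| <= %.3f, |W| <= %.3f\n",
              max(abs(object@b)), max(abs(object@W))))
})

setMethod("show", "ProbabilityTable", function(object) {
  cat(sprintf("ProbabilityTable over %d RVs (%d states)\n",
              object@n, length(object@p)))
  k <- min(8L, length(object@p))
  cat("  first states:", paste(sprintf("%.4f", object@p[seq_len(k)]),
                               collapse = " "), "\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes from %d sources over %.1f ms\n",
              length(object@times),
              length(unique(object@ids)), object@duration))
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d intervals x %d units on [%.1f, %.1f) ms\n",
              nrow(object@states), ncol(object@states),
              object@breakpoints[1],
              object@breakpoints[length(object@breakpoints)]))
})

setMethod("show", "NetworkDefinition", function(object) {
  cat(sprintf("NetworkDefinition: %d neurons (%s), %d synapses, %d external synapses, %d ports\n",
              nrow(object@neurons),
              paste(sprintf("%d %s", as.integer(table(object@neurons$role)),
                            names(table(object@neurons$role))),
                    collapse = ", "),
              nrow(object@synapses), nrow(object@extSynapses),
              length(object@ports)))
})

setMethod("show", "ActivationFit", function(object) {
  cat(sprintf("ActivationFit: nu0 = %.2f Hz, wb0 = %.3f, s = %.3f (digital units)\n",
              object@nu0, object@wb0, object@s))
})

setMethod("show", "VariabilityModel", function(object) {
  cat(sprintf("VariabilityModel: fixed-pattern CV %.0f%% (weights), %.0f%% (tau_syn); trial-to-trial CV %.0f%% (weights)\n",
              100 * object@cvWeightFixed, 100 * object@cvTauSynFixed,
              100 * object@cvWeightTrial))
})

setMethod("show", "ImageDataset", function(object) {
  cat(sprintf("ImageDataset: %d images (12x12 binary), %d classes, %d train / %d test\n",
              nrow(object@images), object@nClasses,
              sum(object@split == "train"), sum(object@split == "test")))
})

setMethod("show", "SamplingNetwork", function(object) {
  cat(sprintf("SamplingNetwork: %d sampling units (%s layout), %s noise backend\n",
              length(object@samplingIds), object@layout$type,
              object@noise$type))
  cat(sprintf("  substrate seed %d, unit scale %.3f nS/digital, %s\n",
              object@substrateSeed, object@unitScale,
              if (length(object@fits)) "calibrated" else "uncalibrated"))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult [%s]: %d grid points", object@protocol,
              length(object@times)))
  if (length(object@summary))
    cat("; ", paste(sprintf("%s = %.4g", names(object@summary),
                            object@summary), collapse = ", "))
  cat("\n")
})
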