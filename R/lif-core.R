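#' Construct network definitions and spike trains
#'
#' \code{networkDefinition()} assembles a validated
#' [NetworkDefinition-class] from a neuron parameter table and synapse
#' tables. \code{spikeTrain()} wraps timestamped events into a validated
#' [SpikeTrain-class].
#'
#' @param neurons data.frame of neuron parameters, one row per neuron (see
#'   [neuronParameters()]).
#' @param synapses data.frame with columns \code{pre}, \code{post},
#'   \code{weight} (nS), \code{kind} ("exc"/"inh"), \code{delay} (ms) and
#'   optionally \code{multapse} (logical).
#' @param extSynapses data.frame attaching external ports to neurons, with
#'   columns \code{port}, \code{post}, \code{weight}, \code{kind},
#'   \code{delay}.
#' @param ports character vector of declared port names; defaults to the
#'   ports referenced by \code{extSynapses}.
#' @return a [NetworkDefinition-class].
#' @export
#' @examples
#' net <- networkDefinition(samplingNeuronParams())
#' net
networkDefinition <- function(neurons, synapses = emptySynapses(),
                              extSynapses = emptyExtSynapses(),
                              ports = unique(extSynapses$port)) {
  if (!"multapse" %in% names(synapses))
    synapses$multapse <- rep(FALSE, nrow(synapses))
  rownames(neurons) <- NULL
  new("NetworkDefinition", neurons = neurons, synapses = synapses,
      extSynapses = extSynapses, ports = as.character(ports))
}

#' @rdname networkDefinition
#' @export
emptySynapses <- function()
  data.frame(pre = integer(), post = integer(), weight = numeric(),
             kind = character(), delay = numeric(), multapse = logical(),
             stringsAsFactors = FALSE)

#' @rdname networkDefinition
#' @export
emptyExtSynapses <- function()
  data.frame(port = character(), post = integer(), weight = numeric(),
             kind = character(), delay = numeric(), stringsAsFactors = FALSE)

#' @param times numeric spike times, ms.
#' @param ids integer source ids, parallel to \code{times}.
#' @param duration observation window length, ms.
#' @rdname networkDefinition
#' @export
spikeTrain <- function(times = numeric(), ids = rep(1L, length(times)),
                       duration = if (length(times)) max(times) else 0) {
  o <- order(times)
  new("SpikeTrain", times = as.numeric(times[o]), ids = as.integer(ids[o]),
      duration = as.numeric(duration))
}

#' Simulate an LIF network
#'
#' Time-stepped integration of a conductance-based LIF network with
#' exponential-kernel synapses (exponential-Euler membrane update, exact
#' exponential conductance decay, threshold detection on the post-step
#' value, spike timestamps on step boundaries). During each refractory
#' window \eqn{[t_{sp}, t_{sp}+\tau_{ref})} the membrane is clamped to
#' \code{V_reset}. The integrator is fully deterministic: identical inputs
#' reproduce identical spike trains bit for bit.
#'
#' @param net a [NetworkDefinition-class].
#' @param inputs named list mapping port names to spike time vectors (or
#'   [SpikeTrain-class] objects) feeding the network's external synapses.
#' @param duration simulated time, ms; spikes are returned on
#'   \code{[0, duration)}.
#' @param dt integration step, ms. Must satisfy
#'   \code{dt <= min(tau_syn, tau_mem, tau_ref) / 4}.
#' @param record integer neuron indices whose membrane potential is
#'   recorded on the step grid.
#' @param u0 initial membrane potentials, mV. The default staggers neuron
#'   \code{i} deterministically between \code{V_reset} and \code{V_thresh}
#'   (golden-ratio phases), so that populations of identical suprathreshold
#'   neurons do not start in pathological lockstep; the assignment is a
#'   fixed function of the neuron index, preserving determinism.
#' @return list with \code{spikes} (a [SpikeTrain-class]) and, when
#'   \code{record} is non-empty, \code{traces}, a neurons x steps matrix
#'   with sample times in \code{attr(, "times")}.
#' @export
#' @examples
#' net <- networkDefinition(biasNeuronParams())
#' out <- simulateNetwork(net, duration = 50, dt = 0.01)
#' diff(spikeTimes(out$spikes))[1]  # ~ tau_ref + charging time
simulateNetwork <- function(net, inputs = list(), duration, dt = 0.1,
                            record = integer(), u0 = NULL) {
  stopifnot(is(net, "NetworkDefinition"))
  if (duration <= 0) stopf("duration must be > 0")
  nrn <- net@neurons
  mintau <- min(nrn$tau_ref, nrn$tau_mem, nrn$tau_syn_exc, nrn$tau_syn_inh)
  if (dt <= 0 || dt > mintau / 4)
    stopf("dt = %g ms is too coarse: need dt <= min(tau)/4 = %g ms",
          dt, mintau / 4)
  unknown <- setdiff(names(inputs), net@ports)
  if (length(unknown))
    stopf("unknown input port(s): %s", paste(unknown, collapse = ", "))

  par <- as.matrix(nrn[, c("V_reset", "E_leak", "V_thresh", "E_inh",
                           "E_exc", "tau_ref", "tau_mem", "C_mem",
                           "tau_syn_exc", "tau_syn_inh")])
  if (is.null(u0)) {
    frac <- (seq_len(nrow(nrn)) * 0.6180339887498949) %% 1
    u0 <- nrn$V_reset + (nrn$V_thresh - nrn$V_reset) * 0.95 * frac
  }
  stopifnot(length(u0) == nrow(nrn))

  syn <- net@synapses
  ext <- net@extSynapses
  # map ports carrying input to train indices; silent ports are dropped
  active <- names(inputs)[vapply(inputs, function(x) {
    if (is(x, "SpikeTrain")) length(x@times) > 0 else length(x) > 0
  }, logical(1))]
  keep <- ext$port %in% active
  extk <- ext[keep, , drop = FALSE]
  trainIdx <- match(extk$port, active)
  evt <- numeric(0); evid <- integer(0)
  if (length(active)) {
    tl <- lapply(inputs[active], function(x)
      if (is(x, "SpikeTrain")) x@times else as.numeric(x))
    evt <- unlist(tl, use.names = FALSE)
    evid <- rep(seq_along(active), lengths(tl))
    o <- order(evt)
    evt <- evt[o]; evid <- evid[o]
    if (length(evt) && evt[1] < 0) stopf("input spike times must be >= 0")
  }

  res <- cpp_lif_simulate(par,
                          as.integer(syn$pre) - 1L, as.integer(syn$post) - 1L,
                          as.numeric(syn$weight),
                          as.integer(syn$kind == "inh"),
                          as.numeric(syn$delay),
                          trainIdx - 1L, as.integer(extk$post) - 1L,
                          as.numeric(extk$weight),
                          as.integer(extk$kind == "inh"),
                          as.numeric(extk$delay),
                          evt, evid - 1L, max(1L, length(active)),
                          duration, dt,
                          as.integer(record) - 1L, as.numeric(u0))

  keepSp <- res$times < duration
  out <- list(spikes = spikeTrain(res$times[keepSp],
                                  as.integer(res$ids[keepSp]) + 1L,
                                  duration = duration))
  if (length(record)) {
    tr <- res$traces
    rownames(tr) <- as.character(record)
    attr(tr, "times") <- seq(0, by = dt, length.out = ncol(tr))
    out$traces <- tr
  }
  out
}

#' Synaptic conductance of an exponential kernel
#'
#' Closed-form conductance at time \code{t} produced by a train of
#' presynaptic spikes through one synapse:
#' \deqn{g(t) = \sum_{sp} J \exp[-(t - t_{sp} - d)/\tau_{syn}]
#'   \,\theta(t - t_{sp} - d),}
#' i.e. each spike contributes \code{J} at onset \code{t_sp + d} and decays
#' exponentially; kernels of successive spikes superpose linearly.
#'
#' @param t evaluation time(s), ms.
#' @param spikes presynaptic spike times (numeric vector or
#'   [SpikeTrain-class]).
#' @param J synaptic weight, nS.
#' @param tauSyn synaptic time constant, ms (> 0).
#' @param delay synaptic delay, ms.
#' @return conductance in nS, one value per entry of \code{t}.
#' @export
#' @examples
#' conductanceAt(c(5, 6, 14), spikes = 5, J = 2, tauSyn = 8, delay = 1)
conductanceAt <- function(t, spikes, J, tauSyn, delay = 0) {
  stopifnot(tauSyn > 0)
  sp <- if (is(spikes, "SpikeTrain")) spikes@times else as.numeric(spikes)
  vapply(t, function(tt) {
    dtv <- tt - sp - delay
    sum(J * exp(-dtv[dtv >= 0] / tauSyn))
  }, numeric(1))
}
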