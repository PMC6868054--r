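#' Neuron parameter sets
#'
#' One-row data frames of LIF neuron parameters (potentials in mV, times in
#' ms, capacitance in nF), in the biological-time frame. Three presets cover
#' the roles used by sampling networks:
#' \describe{
#'   \item{\code{samplingNeuronParams()}}{the neuron encoding a binary RV.
#'     Its leak potential sits exactly at threshold, so the unit is at its
#'     50\% working point when excitatory and inhibitory background balance.}
#'   \item{\code{biasNeuronParams()}}{a suprathreshold-leak neuron
#'     (\code{E_leak > V_thresh}) that fires regularly and implements the
#'     unit's bias through an excitatory/inhibitory synapse pair.}
#'   \item{\code{rnNeuronParams()}}{a suprathreshold-leak inhibitory neuron
#'     of the background random network.}
#' }
#' The leak conductance is always derived as \code{C_mem / tau_mem}.
#'
#' @param role role tag stored with the parameters.
#' @param V_reset reset potential, mV.
#' @param E_leak leak (resting) potential, mV.
#' @param V_thresh threshold potential, mV.
#' @param E_inh,E_exc inhibitory/excitatory reversal potentials, mV.
#' @param tau_ref refractory time, ms.
#' @param tau_mem membrane time constant, ms.
#' @param C_mem membrane capacitance, nF.
#' @param tau_syn_exc,tau_syn_inh synaptic time constants of the neuron's
#'   excitatory and inhibitory inputs, ms.
#' @return one-row data.frame suitable for [networkDefinition()].
#' @export
#' @examples
#' samplingNeuronParams()
#' biasNeuronParams()$E_leak  # suprathreshold: fires regularly
neuronParameters <- function(role = "sampling", V_reset = -35, E_leak = -20,
                             V_thresh = -20, E_inh = -100, E_exc = 60,
                             tau_ref = 4, tau_mem = 7, C_mem = 0.2,
                             tau_syn_exc = 8, tau_syn_inh = 8) {
  stopifnot(tau_ref > 0, tau_mem > 0, C_mem > 0,
            is.finite(c(tau_ref, tau_mem, tau_syn_exc, tau_syn_inh)),
            E_inh < V_thresh, V_thresh < E_exc)
  data.frame(role = role, V_reset = V_reset, E_leak = E_leak,
             V_thresh = V_thresh, E_inh = E_inh, E_exc = E_exc,
             tau_ref = tau_ref, tau_mem = tau_mem, C_mem = C_mem,
             tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
             stringsAsFactors = FALSE)
}

#' @rdname neuronParameters
#' @export
samplingNeuronParams <- function() neuronParameters(role = "sampling")

#' @rdname neuronParameters
#' @export
biasNeuronParams <- function()
  neuronParameters(role = "bias", V_reset = -30, E_leak = 60,
                   V_thresh = -20, tau_ref = 1.5, tau_syn_exc = 5,
                   tau_syn_inh = 5)

#' @rdname neuronParameters
#' @export
rnNeuronParams <- function()
  neuronParameters(role = "random", V_reset = -60, E_leak = -10,
                   V_thresh = -20, tau_ref = 4)

#' Closed-form firing rate of a suprathreshold-leak LIF neuron
#'
#' For a neuron whose leak potential exceeds threshold and that receives no
#' synaptic input, the membrane charges from \code{V_reset} toward
#' \code{E_leak} and crosses threshold after
#' \eqn{\tau_{mem} \ln[(E_{leak}-V_{reset})/(E_{leak}-V_{thresh})]}, giving
#' the inter-spike interval \eqn{ISI = \tau_{ref} + \tau_{mem}\ln(\cdot)}.
#' Used as an independent oracle for the time-stepped integrator and to
#' predict bias-neuron drive rates.
#'
#' @param params one-row neuron parameter data.frame.
#' @return list with elements \code{isi} (ms) and \code{rate} (Hz).
#' @export
#' @examples
#' suprathresholdRate(biasNeuronParams())$isi  # ~2.32 ms
suprathresholdRate <- function(params) {
  if (params$E_leak <= params$V_thresh)
    stopf("neuron is not suprathreshold (E_leak <= V_thresh)")
  isi <- params$tau_ref + params$tau_mem *
    log((params$E_leak - params$V_reset) / (params$E_leak - params$V_thresh))
  list(isi = isi, rate = 1000 / isi)
}
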