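#' Measure sampling-unit activation functions
#'
#' The activation function of a sampling unit is its mean firing rate as a
#' function of the bias weight \eqn{w_b} (digital units). With sufficient
#' background noise the curve takes an approximately logistic shape, the
#' prerequisite for translating Boltzmann parameters onto the substrate.
#' All couplings are turned off and every unit's bias weight is swept over
#' the grid; one run per grid point measures all units simultaneously (each
#' unit has private noise, so units are independent when uncoupled).
#'
#' @param ssn a [SamplingNetwork-class].
#' @param wbGrid bias-weight grid, digital units (signed).
#' @param duration run time per grid point, ms (must be much longer than
#'   the refractory time).
#' @param dt integration step, ms.
#' @param seed integer seed for noise and trial streams.
#' @param variability apply substrate variability (default: follow the
#'   network's model).
#' @return data.frame with columns \code{unit}, \code{wb}, \code{rate} (Hz).
#' @export
measureActivation <- function(ssn, wbGrid = seq(-12, 12, by = 2),
                              duration = 5e3, dt = 0.1, seed = 1L,
                              variability = TRUE) {
  stopifnot(is(ssn, "SamplingNetwork"))
  if (duration <= 0) stopf("duration must be > 0")
  if (!length(wbGrid)) stopf("bias-weight grid must be non-empty")
  n <- nUnits(ssn)
  ssn0 <- setDigitalWeights(ssn, coupling = matrix(0, n, n))
  res <- lapply(seq_along(wbGrid), function(g) {
    ssn0 <- setDigitalWeights(ssn0, bias = rep(wbGrid[g], n))
    run <- ssnRun(ssn0, duration = duration, dt = dt,
                  trialSeed = childSeed(seed, 100L + g),
                  noiseSeed = childSeed(seed, 200L + g),
                  discretize = FALSE, variability = variability)
    counts <- tabulate(run$spikes@ids, nbins = nrow(ssn@net@neurons))
    data.frame(unit = seq_len(n), wb = wbGrid[g],
               rate = 1000 * counts[ssn@samplingIds] / duration)
  })
  do.call(rbind, res)
}

#' Fit the logistic activation function
#'
#' Least-squares fit of \eqn{\nu_0 / \{1 + \exp[-(w_b - w_{b0})/s]\}} to
#' measured (bias weight, rate) points, via Levenberg-Marquardt. Needs at
#' least four points spanning the transition; degenerate (all-equal-rate)
#' input is rejected.
#'
#' @param wb bias weights, digital units.
#' @param rate mean rates, Hz (same length).
#' @return an [ActivationFit-class].
#' @export
#' @examples
#' wb <- seq(-10, 10, 2)
#' r <- 100 / (1 + exp(-(wb - 3) / 2))
#' fitActivation(wb, r)
fitActivation <- function(wb, rate) {
  stopifnot(length(wb) == length(rate))
  if (length(wb) < 4L) stopf("need at least 4 points to fit")
  if (diff(range(rate)) < 1e-9)
    stopf("degenerate activation data: all rates equal")
  o <- order(wb)
  wb <- wb[o]; rate <- rate[o]
  nu0 <- max(rate) * 1.02 + 1e-6
  wb0 <- stats::approx(cummax(rate) + seq_along(rate) * 1e-9, wb,
                       xout = nu0 / 2, rule = 2)$y
  s0 <- max(diff(range(wb)) / 8, 1e-3)
  cf <- tryCatch({
    fit <- minpack.lm::nlsLM(
      rate ~ nu0 * stats::plogis((wb - wb0) / s),
      start = list(nu0 = nu0, wb0 = wb0, s = s0),
      lower = c(1e-6, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200),
      data = data.frame(wb = wb, rate = rate))
    stats::coef(fit)
  }, error = function(e) {
    # very sharp transitions can defeat the gradient-based fit; fall back
    # to direct least squares over (nu0, wb0, log s)
    obj <- function(th)
      sum((rate - th[1] * stats::plogis((wb - th[2]) / exp(th[3])))^2)
    op <- stats::optim(c(nu0, wb0, log(s0)), obj,
                       control = list(maxit = 2000, reltol = 1e-12))
    c(nu0 = op$par[1], wb0 = op$par[2], s = exp(op$par[3]))
  })
  new("ActivationFit", nu0 = unname(cf["nu0"]), wb0 = unname(cf["wb0"]),
      s = unname(cf["s"]))
}

#' Calibrate every unit of a sampling network
#'
#' Runs [measureActivation()] and [fitActivation()] for all units, stores
#' the per-unit fits in the network, and (optionally) calibrates the
#' empirical coupling conversion factor. The fits are the basis for
#' [translateParameters()].
#'
#' @inheritParams measureActivation
#' @param measureKappa also run the two-unit coupling probe of
#'   [couplingScale()] and store the result.
#' @return the [SamplingNetwork-class] with filled \code{fits} (and
#'   \code{kappa}).
#' @export
calibrateNetwork <- function(ssn, wbGrid = seq(-12, 12, by = 2),
                             duration = 5e3, dt = 0.1, seed = 1L,
                             measureKappa = TRUE) {
  act <- measureActivation(ssn, wbGrid, duration, dt, seed)
  ssn@fits <- lapply(seq_len(nUnits(ssn)), function(k) {
    d <- act[act$unit == k, ]
    fitActivation(d$wb, d$rate)
  })
  if (measureKappa)
    ssn@kappa <- couplingScale(ssn, "empirical", seed = childSeed(seed, 9L))
  ssn
}

#' Coupling scale of a sampling network
#'
#' The single global factor \eqn{\kappa} converting abstract couplings into
#' digital weights (per geometric-mean activation width; see
#' [translateParameters()]).
#'
#' \code{method = "analytic"} uses a first-order argument: the mean
#' conductance a presynaptic on-state delivers during one refractory window
#' (\eqn{J (\tau_{syn}/\tau_{ref})(1 - e^{-\tau_{ref}/\tau_{syn}})} per unit
#' weight) is matched to the mean conductance of an equivalent bias-weight
#' offset (\eqn{J \nu_b \tau_{syn}} per unit, with \eqn{\nu_b} the
#' bias-neuron rate). This ignores the kernel tail that outlasts the
#' on-state and the membrane's reaction lag, and overestimates \eqn{\kappa}
#' by roughly a factor two at the default working point.
#'
#' \code{method = "empirical"} (the default used by calibration) measures
#' \eqn{\kappa} directly, the way analog substrates are commissioned: an
#' ideal (variability-free) two-unit probe network with the same neuron
#' parameters and noise backend is biased to its midpoint, a known digital
#' coupling \eqn{\pm w_d} is written, and the effective Boltzmann coupling
#' is read off the sampled two-unit joint as
#' \eqn{\hat W = \ln[p_{11} p_{00} / (p_{10} p_{01})]}; then
#' \eqn{\kappa = w_d / (\hat W \sqrt{s_1 s_2})}, averaged over both signs.
#'
#' @param ssn a [SamplingNetwork-class].
#' @param method "empirical" or "analytic".
#' @param probeWeight digital coupling magnitude of the probe.
#' @param duration probe sampling time per sign, ms.
#' @param seed integer seed of the probe runs.
#' @return dimensionless scalar factor.
#' @export
couplingScale <- function(ssn, method = c("empirical", "analytic"),
                          probeWeight = 6, duration = 2e5, seed = 1L) {
  method <- match.arg(method)
  bias <- ssn@net@neurons[ssn@biasIds[1], ]
  smp <- ssn@net@neurons[ssn@samplingIds[1], ]
  if (method == "analytic") {
    nuB <- suprathresholdRate(bias)$rate / 1000  # spikes per ms
    tauS <- smp$tau_syn_exc
    tauR <- smp$tau_ref
    biasG <- nuB * tauS
    onG <- (tauS / tauR) * (1 - exp(-tauR / tauS))
    return(biasG / onG)
  }
  probe <- buildSamplingNetwork(
    2, noise = ssn@noise$type,
    noiseRate = if (!is.null(ssn@noise$rate)) ssn@noise$rate else 300,
    noiseWeight = if (!is.null(ssn@noise$weight)) ssn@noise$weight else 30,
    rnSpec = if (!is.null(ssn@noise$rnSpec)) ssn@noise$rnSpec
             else randomNetworkSpec(),
    unitScale = ssn@unitScale, variability = variabilityModel(0, 0, 0),
    samplingParams = ssn@net@neurons[ssn@samplingIds[1], ],
    biasParams = ssn@net@neurons[ssn@biasIds[1], ],
    substrateSeed = 1L)
  act <- measureActivation(probe, wbGrid = seq(-12, 12, by = 3),
                           duration = 1e4, seed = childSeed(seed, 5L),
                           variability = FALSE)
  fits <- lapply(1:2, function(k) {
    d <- act[act$unit == k, ]
    fitActivation(d$wb, d$rate)
  })
  wb0 <- vapply(fits, function(f) f@wb0, numeric(1))
  s <- vapply(fits, function(f) f@s, numeric(1))
  tauR <- smp$tau_ref
  kap <- vapply(c(-probeWeight, probeWeight), function(wd) {
    probe2 <- setDigitalWeights(probe, bias = wb0,
                                coupling = matrix(c(0, wd, wd, 0), 2))
    run <- ssnRun(probe2, duration = duration,
                  noiseSeed = childSeed(seed, 7L + (wd > 0)),
                  discretize = FALSE, variability = FALSE)
    st <- extractStates(run$spikes, tauR, c(80, duration),
                        ids = probe@samplingIds)
    p <- probs(empiricalJoint(st))
    What <- log(p[4] * p[1] / (p[2] * p[3]))
    wd / (What * sqrt(s[1] * s[2]))
  }, numeric(1))
  mean(kap)
}

#' Translate Boltzmann parameters to digital weights
#'
#' Maps a target's dimensionless parameters onto the substrate using the
#' per-unit activation fits: bias \eqn{b_i} becomes the bias weight
#' \eqn{w_b = w_{b0,i} + s_i b_i} (the logistic midpoint is the zero-bias
#' point, the width is the digital equivalent of one bias unit), and
#' coupling \eqn{W_{ij}} becomes a digital weight
#' \eqn{\kappa \sqrt{s_i s_j} W_{ij}}, with the widths combined by geometric
#' mean (symmetric treatment of the synapse pair) and \eqn{\kappa} the
#' bias-to-coupling conversion factor from [couplingScale()]. The sign of
#' each digital weight selects the excitatory or inhibitory member of its
#' synapse pair when the network is realized.
#'
#' @param ssn a calibrated [SamplingNetwork-class] (see
#'   [calibrateNetwork()]).
#' @param target a [BoltzmannTarget-class] of matching size.
#' @param kappa coupling conversion factor; defaults to the empirically
#'   calibrated value stored by [calibrateNetwork()], falling back to a
#'   fresh [couplingScale()] probe.
#' @return the [SamplingNetwork-class] with translated digital weights
#'   installed.
#' @export
translateParameters <- function(ssn, target,
                                kappa = if (length(ssn@kappa)) ssn@kappa
                                        else couplingScale(ssn)) {
  n <- nUnits(ssn)
  if (length(ssn@fits) != n)
    stopf("network must be calibrated first (missing activation fits)")
  if (nUnits(target) != n) stopf("target size must match the network")
  wb0 <- vapply(ssn@fits, function(f) f@wb0, numeric(1))
  s <- vapply(ssn@fits, function(f) f@s, numeric(1))
  bias <- wb0 + s * targetBiases(target)
  sgeo <- sqrt(outer(s, s))
  W <- kappa * sgeo * targetWeights(target)
  mask <- matrix(0, n, n)
  mask[ssn@pairs] <- 1
  setDigitalWeights(ssn, bias, W * (mask + t(mask)))
}
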