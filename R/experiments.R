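# Internal: ExperimentResult constructor.
expResult <- function(protocol, times, metric, summary = numeric(),
                      seeds = integer(), config = list(), detail = list()) {
  new("ExperimentResult", protocol = protocol, times = as.numeric(times),
      metric = as.numeric(metric), summary = summary,
      seeds = as.integer(seeds), config = config, detail = detail)
}

# Internal: merge two named port->times input lists (concatenating shared
# ports, keeping times sorted).
mergeInputs <- function(a, b) {
  for (p in names(b))
    a[[p]] <- if (is.null(a[[p]])) b[[p]] else sort(c(a[[p]], b[[p]]))
  a
}

# Internal: trailing-window on-state occupancy. `iv` is one unit's merged
# on-interval list (start, end); returns occupancy of [t - window, t] for
# each t, vectorized over times.
occupancyCurve <- function(iv, times, window) {
  if (!length(iv$start)) return(numeric(length(times)) * 0)
  cumOn <- function(t)
    colSums(pmax(outer(-iv$start, t, "+"), 0) -
              pmax(outer(-iv$end, t, "+"), 0))
  (cumOn(times) - cumOn(times - window)) / window
}

# Internal: cumulative-time DKL trace. Given a StateSequence and a target
# table, returns DKL(empirical over [t0, t] || target) for each grid time.
dklTrace <- function(states, targetTable, grid) {
  n <- ncol(states@states)
  idx <- as.vector(states@states %*% 2^(seq_len(n) - 1)) + 1
  s <- states@breakpoints[-length(states@breakpoints)]
  e <- states@breakpoints[-1]
  vapply(grid, function(t) {
    dur <- pmin(e, t) - s
    keep <- dur > 0
    p <- numeric(2^n)
    tab <- rowsum(dur[keep], idx[keep])
    p[as.integer(rownames(tab))] <- tab
    dkl(probabilityTable(p, n), targetTable)
  }, numeric(1))
}

#' Joint sampling experiment
#'
#' Samples a (trained or translated) network for a long run and tracks the
#' convergence of the time-weighted empirical joint toward the target:
#' DKL(empirical over \code{[0, t]} against the target joint) at each grid
#' time. Re-running with identical seeds reproduces the trace bit for bit.
#'
#' @param ssn a [SamplingNetwork-class] with weights installed.
#' @param target the [BoltzmannTarget-class] it represents.
#' @param duration test run length, ms.
#' @param grid evaluation times, ms; default 20 points log-spaced over two
#'   decades up to \code{duration}.
#' @param dt integration step, ms.
#' @param trialSeed,noiseSeed seeds of the run's analog rewrite and noise.
#' @param discretize,variability substrate constraint switches.
#' @return an [ExperimentResult-class] (protocol "sampling"); the final
#'   grid value is in \code{summary["finalDkl"]}.
#' @export
samplingExperiment <- function(ssn, target, duration = 1e5, grid = NULL,
                               dt = 0.1, trialSeed = 1L, noiseSeed = 2L,
                               discretize = TRUE, variability = TRUE) {
  if (is.null(grid))
    grid <- unique(round(exp(seq(log(duration / 100), log(duration),
                                 length.out = 20))))
  run <- ssnRun(ssn, duration = duration, dt = dt, trialSeed = trialSeed,
                noiseSeed = noiseSeed, discretize = discretize,
                variability = variability)
  tauRef <- ssn@net@neurons$tau_ref[ssn@samplingIds]
  st <- extractStates(run$spikes, tauRef, c(0, duration),
                      ids = ssn@samplingIds)
  tr <- dklTrace(st, targetJoint(target), grid)
  expResult("sampling", grid, tr,
            summary = c(finalDkl = tr[length(tr)]),
            seeds = c(trial = trialSeed, noise = noiseSeed),
            config = list(duration = duration, dt = dt,
                          discretize = discretize,
                          variability = variability))
}

#' Conditional inference experiment
#'
#' Clamps a subset of units to fixed values (multapse clamping trains) and
#' compares the sampled conditional distribution of the free units to the
#' analytic conditional of the target: DKL over the free-state subspace at
#' each grid time. Because the free state space is smaller, this trace
#' typically reaches its floor at shorter sampling times than the joint
#' trace of the same network.
#'
#' @inheritParams samplingExperiment
#' @param clamp named vector mapping unit indices to clamped values, e.g.
#'   \code{c("1" = 0, "2" = 1)}.
#' @return an [ExperimentResult-class] (protocol "inference");
#'   \code{detail$clampOccupancy} holds the measured occupancy of each
#'   clamped unit.
#' @export
inferenceExperiment <- function(ssn, target, clamp = c("1" = 0, "2" = 1),
                                duration = 1e5, grid = NULL, dt = 0.1,
                                trialSeed = 1L, noiseSeed = 2L,
                                discretize = TRUE, variability = TRUE) {
  n <- nUnits(ssn)
  cidx <- as.integer(names(clamp))
  if (length(cidx) >= n) stopf("cannot clamp all units")
  free <- setdiff(seq_len(n), cidx)
  if (is.null(grid))
    grid <- unique(round(exp(seq(log(duration / 100), log(duration),
                                 length.out = 20))))
  pat <- as.integer(clamp)
  names(pat) <- cidx
  run <- ssnRun(ssn, duration = duration, dt = dt, trialSeed = trialSeed,
                noiseSeed = noiseSeed, discretize = discretize,
                variability = variability, clampPattern = pat)
  tauRef <- ssn@net@neurons$tau_ref[ssn@samplingIds]
  stFree <- extractStates(run$spikes, tauRef[free], c(0, duration),
                          ids = ssn@samplingIds[free])
  cond <- conditionalJoint(target, clamp)
  tr <- dklTrace(stFree, cond, grid)
  stCl <- extractStates(run$spikes, tauRef[cidx], c(0, duration),
                        ids = ssn@samplingIds[cidx])
  occ <- colSums(diff(stCl@breakpoints) * stCl@states) / duration
  expResult("inference", grid, tr,
            summary = c(finalDkl = tr[length(tr)]),
            seeds = c(trial = trialSeed, noise = noiseSeed),
            config = list(clamp = as.list(clamp), duration = duration,
                          dt = dt),
            detail = list(clampOccupancy = occ, free = free))
}

#' Classify images with a hierarchical sampling network
#'
#' Presents each image to the visible layer (excitatory clamp for 1-pixels,
#' inhibitory for 0-pixels) for \code{presentMs} and reads the predicted
#' label as the label neuron with the highest spike count in the window.
#' Ties break to the lowest label index and are flagged; an all-silent
#' label layer counts as an error and is flagged. Only spikes are read out,
#' no membrane traces.
#'
#' @param ssn a trained hierarchical [SamplingNetwork-class].
#' @param images integer matrix (images x 144) of binary pixels.
#' @param labels optional true class labels (1-based) for the error ratio.
#' @param presentMs presentation time per image, ms.
#' @param dt integration step, ms.
#' @param trialSeed,noiseSeed seeds (one analog rewrite for the whole run).
#' @param discretize,variability substrate constraint switches.
#' @return an [ExperimentResult-class] (protocol "classify"): \code{metric}
#'   is the per-image 0/1 error (NA-free; 0 when no labels are given),
#'   \code{summary["errorRatio"]} the error ratio,
#'   \code{detail$predicted}/\code{detail$flags} the predictions and
#'   tie/silent flags.
#' @export
classify <- function(ssn, images, labels = NULL, presentMs = 500, dt = 0.1,
                     trialSeed = 1L, noiseSeed = 2L, discretize = TRUE,
                     variability = TRUE) {
  stopifnot(ssn@layout$type == "hierarchical")
  if (presentMs <= 0) stopf("presentation time must be > 0")
  lay <- ssn@layout
  if (ncol(images) != length(lay$visible))
    stopf("image size must match the visible layer")
  net <- realizeNetwork(ssn, trialSeed = trialSeed, discretize = discretize,
                        variability = variability)
  visIds <- ssn@samplingIds[lay$visible]
  labIds <- ssn@samplingIds[lay$label]
  net <- addClampPorts(net, visIds, weight = 15 * ssn@unitScale)
  predicted <- integer(nrow(images))
  flags <- character(nrow(images))
  for (i in seq_len(nrow(images))) {
    inputs <- noiseInputs(ssn, presentMs, childSeed(noiseSeed, i))
    inputs <- mergeInputs(inputs,
                          clampPortInputs(visIds, images[i, ], presentMs))
    sim <- simulateNetwork(net, inputs, duration = presentMs, dt = dt)
    counts <- tabulate(sim$spikes@ids, nbins = nrow(net@neurons))[labIds]
    if (all(counts == 0)) {
      predicted[i] <- NA_integer_
      flags[i] <- "silent"
    } else {
      predicted[i] <- which.max(counts)  # which.max: lowest index on ties
      if (sum(counts == max(counts)) > 1L) flags[i] <- "tie"
    }
  }
  err <- if (is.null(labels)) numeric(nrow(images))
         else as.numeric(is.na(predicted) | predicted != labels)
  expResult("classify", seq_len(nrow(images)), err,
            summary = c(errorRatio = mean(err)),
            seeds = c(trial = trialSeed, noise = noiseSeed),
            config = list(presentMs = presentMs, dt = dt),
            detail = list(predicted = predicted, flags = flags))
}

#' Pattern completion on partially occluded images
#'
#' For each image, a fraction of visible neurons receives no input (salt &
#' pepper or patch occlusion); the rest are clamped to the image. Between
#' images the visible layer is scrambled by random input for
#' \code{interMs}. The reconstruction error is the mean squared error over
#' the occluded pixels between the data values and the reconstructed binary
#' states (trailing 10 ms box-filtered occupancy, thresholded at 1/2),
#' evaluated on a 5 ms grid after stimulus onset and averaged over images.
#' Chance level is 1/2. A label-error trace over the same grid is recorded
#' alongside.
#'
#' @param ssn a trained hierarchical [SamplingNetwork-class].
#' @param images integer matrix (images x 144).
#' @param labels optional true labels for the label-error trace.
#' @param scheme occlusion scheme, \code{"saltpepper"} or \code{"patch"}.
#' @param fraction occluded fraction (default 25\%).
#' @param presentMs presentation time per image, ms.
#' @param interMs random-input scramble time before each image, ms.
#' @param gridMs MSE evaluation step, ms.
#' @param smoothMs trailing box-filter width, ms.
#' @param seed seed for occlusion masks and scramble patterns.
#' @inheritParams classify
#' @return an [ExperimentResult-class] (protocol "completion"):
#'   \code{metric} is the image-averaged MSE(t) on the grid;
#'   \code{detail$labelError} the label-error trace, \code{detail$masks}
#'   the occlusion masks.
#' @export
patternComplete <- function(ssn, images, labels = NULL,
                            scheme = c("saltpepper", "patch"),
                            fraction = 0.25, presentMs = 500, interMs = 100,
                            gridMs = 5, smoothMs = 10, seed = 1L, dt = 0.1,
                            trialSeed = 1L, noiseSeed = 2L,
                            discretize = TRUE, variability = TRUE) {
  stopifnot(ssn@layout$type == "hierarchical")
  scheme <- match.arg(scheme)
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  lay <- ssn@layout
  net <- realizeNetwork(ssn, trialSeed = trialSeed, discretize = discretize,
                        variability = variability)
  visIds <- ssn@samplingIds[lay$visible]
  labIds <- ssn@samplingIds[lay$label]
  net <- addClampPorts(net, visIds, weight = 15 * ssn@unitScale)
  grid <- seq(gridMs, presentMs, by = gridMs)
  tauRefVis <- ssn@net@neurons$tau_ref[visIds]
  total <- interMs + presentMs
  mse <- matrix(0, nrow(images), length(grid))
  labErr <- matrix(0, nrow(images), length(grid))
  masks <- matrix(FALSE, nrow(images), ncol(images))
  for (i in seq_len(nrow(images))) {
    occ <- occlude(images[i, ], scheme, fraction, childSeed(seed, i))
    masks[i, ] <- occ$mask
    scramble <- withSeed(childSeed(seed, 10000L + i),
                         stats::rbinom(length(visIds), 1L, 0.5))
    inputs <- noiseInputs(ssn, total, childSeed(noiseSeed, i))
    inputs <- mergeInputs(inputs,
                          clampPortInputs(visIds, scramble, interMs))
    keep <- !occ$mask
    inputs <- mergeInputs(inputs,
                          clampPortInputs(visIds[keep], images[i, keep],
                                          total, from = interMs))
    sim <- simulateNetwork(net, inputs, duration = total, dt = dt)
    ivOcc <- onIntervals(sim$spikes, tauRefVis[occ$mask], c(0, total),
                         visIds[occ$mask])
    recon <- t(vapply(ivOcc, function(iv)
      as.numeric(occupancyCurve(iv, interMs + grid, smoothMs) > 0.5),
      numeric(length(grid))))
    mse[i, ] <- colMeans((recon - images[i, occ$mask])^2)
    if (!is.null(labels)) {
      labSp <- sim$spikes@times[sim$spikes@ids %in% labIds]
      labId <- sim$spikes@ids[sim$spikes@ids %in% labIds]
      labErr[i, ] <- vapply(grid, function(t) {
        inWin <- labSp >= interMs & labSp < interMs + t
        if (!any(inWin)) return(1)
        counts <- tabulate(match(labId[inWin], labIds),
                           nbins = length(labIds))
        as.numeric(which.max(counts) != labels[i])
      }, numeric(1))
    }
  }
  expResult("completion", grid, colMeans(mse),
            summary = c(finalMse = mean(mse[, length(grid)]),
                        longRunMse = mean(mse[, grid >= presentMs / 2])),
            seeds = c(trial = trialSeed, noise = noiseSeed, mask = seed),
            config = list(scheme = scheme, fraction = fraction,
                          presentMs = presentMs, interMs = interMs),
            detail = list(labelError = colMeans(labErr), masks = masks))
}

#' Guided dreaming
#'
#' Runs the network freely (visible and hidden layers unclamped) while the
#' label layer is periodically clamped to an enforced one-hot code: per
#' schedule entry, \code{interMs} of random input to the visible layer
#' (facilitating image changes) followed by \code{perLabelMs} with exactly
#' one label neuron clamped on and all others clamped off. Snapshots of the
#' visible layer (trailing box-filtered occupancy, grayscale in [0, 1]) are
#' recorded on a regular grid within each label segment.
#'
#' @param ssn a trained hierarchical [SamplingNetwork-class].
#' @param labelSeq integer sequence of label indices to clamp (each entry
#'   must name exactly one label unit).
#' @param perLabelMs clamped time per schedule entry, ms.
#' @param interMs random visible input between entries, ms.
#' @param snapshotEveryMs snapshot spacing within a segment, ms.
#' @param smoothMs trailing box-filter width, ms.
#' @param seed seed for the scramble patterns.
#' @param labelMultapse number of parallel clamp synapses per label neuron.
#'   One-hot coding must be enforced against the full trained hidden-layer
#'   fan-in, which can exceed what the standard 5-fold multapse delivers;
#'   multapses are the substrate's mechanism for surpassing the
#'   single-synapse weight ceiling.
#' @inheritParams classify
#' @return an [ExperimentResult-class] (protocol "dream"): \code{metric} is
#'   the mean visible activity per snapshot; \code{detail$snapshots} a
#'   (snapshots x pixels) matrix, \code{detail$snapshotLabel} the clamped
#'   label per snapshot, \code{detail$labelOccupancy} the per-segment
#'   occupancy of the clamped label neuron.
#' @export
guidedDream <- function(ssn, labelSeq, perLabelMs = 500, interMs = 100,
                        snapshotEveryMs = 50, smoothMs = 10, seed = 1L,
                        labelMultapse = 20L, dt = 0.1, trialSeed = 1L,
                        noiseSeed = 2L, discretize = TRUE,
                        variability = TRUE) {
  stopifnot(ssn@layout$type == "hierarchical")
  lay <- ssn@layout
  nLab <- length(lay$label)
  labelSeq <- as.integer(labelSeq)
  if (any(labelSeq < 1L | labelSeq > nLab))
    stopf("schedule entries must name one of the %d label units", nLab)
  net <- realizeNetwork(ssn, trialSeed = trialSeed, discretize = discretize,
                        variability = variability)
  visIds <- ssn@samplingIds[lay$visible]
  labIds <- ssn@samplingIds[lay$label]
  net <- addClampPorts(net, visIds, weight = 15 * ssn@unitScale)
  net <- addClampPorts(net, labIds, weight = 15 * ssn@unitScale,
                       multapse = labelMultapse)
  seg <- interMs + perLabelMs
  total <- seg * length(labelSeq)
  inputs <- noiseInputs(ssn, total, noiseSeed)
  for (k in seq_along(labelSeq)) {
    t0 <- (k - 1) * seg
    # the label layer is one-hot clamped at all times; the random visible
    # input overlaps the start of each label segment to break the previous
    # image's attractor
    scramble <- withSeed(childSeed(seed, k),
                         stats::rbinom(length(visIds), 1L, 0.5))
    inputs <- mergeInputs(inputs,
                          clampPortInputs(visIds, scramble, t0 + interMs,
                                          from = t0))
    oneHot <- as.integer(seq_len(nLab) == labelSeq[k])
    inputs <- mergeInputs(inputs,
                          clampPortInputs(labIds, oneHot, t0 + seg,
                                          from = t0,
                                          multapse = labelMultapse))
  }
  sim <- simulateNetwork(net, inputs, duration = total, dt = dt)
  tauRefVis <- ssn@net@neurons$tau_ref[visIds]
  ivVis <- onIntervals(sim$spikes, tauRefVis, c(0, total), visIds)
  snapT <- unlist(lapply(seq_along(labelSeq), function(k)
    (k - 1) * seg + interMs + seq(snapshotEveryMs, perLabelMs,
                                  by = snapshotEveryMs)), use.names = FALSE)
  snaps <- t(vapply(ivVis, function(iv)
    occupancyCurve(iv, snapT, smoothMs), numeric(length(snapT))))
  snapLab <- rep(labelSeq, each = length(snapT) / length(labelSeq))
  tauRefLab <- ssn@net@neurons$tau_ref[labIds]
  labOcc <- vapply(seq_along(labelSeq), function(k) {
    t0 <- (k - 1) * seg + interMs
    iv <- onIntervals(sim$spikes, tauRefLab[labelSeq[k]], c(t0, t0 + perLabelMs),
                      labIds[labelSeq[k]])[[1]]
    sum(iv$end - iv$start) / perLabelMs
  }, numeric(1))
  expResult("dream", snapT, colMeans(snaps),
            summary = c(nSnapshots = length(snapT)),
            seeds = c(trial = trialSeed, noise = noiseSeed, scramble = seed),
            config = list(labelSeq = labelSeq, perLabelMs = perLabelMs,
                          interMs = interMs),
            detail = list(snapshots = t(snaps), snapshotLabel = snapLab,
                          labelOccupancy = labOcc))
}
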