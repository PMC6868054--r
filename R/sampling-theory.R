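#' Boltzmann targets
#'
#' \code{boltzmannTarget()} validates and wraps a coupling matrix and bias
#' vector into a [BoltzmannTarget-class]. \code{randomTarget()} draws a
#' random target in the scheme used for the sampling benchmarks: every bias
#' and every upper-triangle coupling i.i.d. from
#' \eqn{2[\mathrm{Beta}(0.5,0.5) - 0.5]}, a U-shaped density on
#' \eqn{[-1, 1]} that favours larger absolute parameter values and hence
#' rougher energy landscapes; the matrix is then symmetrized.
#'
#' @param W symmetric zero-diagonal numeric matrix of couplings.
#' @param b numeric bias vector.
#' @param n number of random variables.
#' @param seed integer seed; draws are reproducible.
#' @return a [BoltzmannTarget-class].
#' @export
#' @examples
#' tgt <- randomTarget(5, seed = 42)
#' range(targetWeights(tgt))  # within [-1, 1]
boltzmannTarget <- function(W, b) {
  new("BoltzmannTarget", W = as.matrix(W), b = as.numeric(b))
}

#' @rdname boltzmannTarget
#' @export
randomTarget <- function(n, seed) {
  stopifnot(n >= 1)
  withSeed(seed, {
    b <- 2 * (stats::rbeta(n, 0.5, 0.5) - 0.5)
    W <- matrix(0, n, n)
    if (n > 1) {
      up <- upper.tri(W)
      W[up] <- 2 * (stats::rbeta(sum(up), 0.5, 0.5) - 0.5)
      W <- W + t(W)
    }
    boltzmannTarget(W, b)
  })
}

#' Probability tables
#'
#' \code{probabilityTable()} normalizes a non-negative vector over the
#' \code{2^n} binary states into a [ProbabilityTable-class] (state order as
#' in [stateMatrix()]). \code{targetJoint()} computes the exact joint of a
#' [BoltzmannTarget-class] by explicit enumeration (n <= 20).
#' \code{conditionalJoint()} clamps a subset of variables to fixed values
#' and renormalizes over the free ones, returning a table over the free
#' variables in increasing index order.
#'
#' @param p non-negative numeric vector of length \code{2^n}.
#' @param n number of binary random variables.
#' @param target a [BoltzmannTarget-class].
#' @param clamp named vector/list mapping variable indices to clamped values
#'   in \{0, 1\}, e.g. \code{c("1" = 0, "2" = 1)}.
#' @return a [ProbabilityTable-class].
#' @export
#' @examples
#' tgt <- boltzmannTarget(matrix(0, 1, 1), b = log(3))
#' probs(targetJoint(tgt))  # (0.25, 0.75)
probabilityTable <- function(p, n = as.integer(round(log2(length(p))))) {
  s <- sum(p)
  if (!is.finite(s) || s <= 0) stopf("probabilities must have a positive sum")
  new("ProbabilityTable", n = as.integer(n), p = as.numeric(p) / s)
}

#' @rdname probabilityTable
#' @export
targetJoint <- function(target) {
  stopifnot(is(target, "BoltzmannTarget"))
  n <- nUnits(target)
  if (n > 20) stopf("explicit enumeration limited to n <= 20 (got %d)", n)
  Z <- stateMatrix(n)
  e <- 0.5 * rowSums((Z %*% target@W) * Z) + as.vector(Z %*% target@b)
  w <- exp(e - max(e))
  probabilityTable(w, n)
}

#' @rdname probabilityTable
#' @export
conditionalJoint <- function(target, clamp = NULL) {
  joint <- targetJoint(target)
  if (is.null(clamp) || length(clamp) == 0L) return(joint)
  idx <- as.integer(names(clamp))
  val <- as.integer(unlist(clamp))
  n <- nUnits(target)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > n))
    stopf("clamped indices must be distinct and within 1..%d", n)
  if (!all(val %in% c(0L, 1L))) stopf("clamp values must be 0 or 1")
  free <- setdiff(seq_len(n), idx)
  if (!length(free)) stopf("clamping all variables leaves no free RV")
  Z <- stateMatrix(n)
  sel <- rowSums(Z[, idx, drop = FALSE] !=
                   matrix(val, nrow(Z), length(idx), byrow = TRUE)) == 0
  sub <- probs(joint)[sel]
  # rows with sel = TRUE are ordered by the free bits (low index fastest)
  probabilityTable(sub, length(free))
}

#' Refractory-based state extraction
#'
#' Converts spikes into the binary network state \eqn{z(t)}: unit \eqn{k} is
#' on exactly on the union of its refractory windows
#' \eqn{[t_{sp}, t_{sp} + \tau_{ref,k})}. The result is a piecewise-constant
#' [StateSequence-class] with breakpoints at every on/off transition inside
#' the observation window.
#'
#' @param spikes a [SpikeTrain-class].
#' @param tauRef refractory time(s), ms: a scalar or one value per unit.
#' @param window numeric \code{c(t0, t1)} observation window, ms; must lie
#'   within the simulated range.
#' @param ids neuron ids (in \code{spikes}) of the sampling units, in unit
#'   order. Defaults to \code{1:n} with \code{n = max(spikeIds(spikes))}.
#' @return a [StateSequence-class] over \code{length(ids)} units.
#' @export
#' @examples
#' st <- extractStates(spikeTrain(c(10, 12), c(1L, 1L), duration = 20),
#'                     tauRef = 4, window = c(0, 20))
#' st  # on-state on [10, 16)
extractStates <- function(spikes, tauRef, window, ids = NULL) {
  stopifnot(is(spikes, "SpikeTrain"))
  if (is.null(ids)) ids <- seq_len(max(1L, suppressWarnings(max(spikes@ids,
                                                                0L))))
  n <- length(ids)
  tauRef <- rep_len(tauRef, n)
  stopifnot(all(tauRef > 0))
  t0 <- window[1]; t1 <- window[2]
  if (t1 <= t0) stopf("observation window must have positive length")
  if (t0 < 0 || t1 > spikes@duration + 1e-9)
    stopf("window [%g, %g] outside the simulated range [0, %g]",
          t0, t1, spikes@duration)
  iv <- onIntervals(spikes, tauRef, c(t0, t1), ids)
  bp <- sort(unique(c(t0, t1, unlist(lapply(iv, function(x)
    c(x$start, x$end)), use.names = FALSE))))
  bp <- bp[bp >= t0 & bp <= t1]
  m <- length(bp) - 1L
  # the state is constant on [bp[i], bp[i+1]); evaluate it at the midpoint
  tm <- (bp[-1] + bp[-length(bp)]) / 2
  states <- vapply(seq_len(n), function(k) {
    as.integer(findInterval(tm, iv[[k]]$start) >
                 findInterval(tm, iv[[k]]$end))
  }, integer(m))
  new("StateSequence", breakpoints = bp, states = matrix(states, m, n))
}

# Merged on-intervals per unit, clipped to the window. Returns a list (one
# per unit) of list(start, end) sorted disjoint intervals.
onIntervals <- function(spikes, tauRef, window, ids) {
  t0 <- window[1]; t1 <- window[2]
  lapply(seq_along(ids), function(k) {
    sp <- spikes@times[spikes@ids == ids[k]]
    sp <- sp[sp + tauRef[k] > t0 & sp < t1]
    if (!length(sp)) return(list(start = numeric(), end = numeric()))
    s <- sp; e <- sp + tauRef[k]
    # merge overlapping refractory windows (spikes cannot occur inside a
    # refractory window, but be robust to tauRef conventions)
    keep <- c(TRUE, s[-1] > cummax(e[-length(e)]) + 1e-12)
    grp <- cumsum(keep)
    start <- tapply(s, grp, min)
    end <- tapply(e, grp, max)
    list(start = pmax(as.numeric(start), t0), end = pmin(as.numeric(end), t1))
  })
}

#' Time-weighted empirical distribution of sampled states
#'
#' The empirical joint assigns each binary state the fraction of observation
#' time the network spent in it: \eqn{p(z)} = (total duration in state
#' \eqn{z}) / (window length).
#'
#' @param states a [StateSequence-class] (n <= 20 units).
#' @return a [ProbabilityTable-class].
#' @export
#' @examples
#' st <- extractStates(spikeTrain(10, 1L, duration = 20), 4, c(0, 20))
#' probs(empiricalJoint(st))  # 0.8 off, 0.2 on
empiricalJoint <- function(states) {
  stopifnot(is(states, "StateSequence"))
  n <- ncol(states@states)
  if (n > 20) stopf("explicit state tables limited to n <= 20")
  dur <- diff(states@breakpoints)
  if (!length(dur) || sum(dur) <= 0)
    stopf("observation window must have positive length")
  idx <- as.vector(states@states %*% 2^(seq_len(n) - 1)) + 1
  p <- numeric(2^n)
  tab <- rowsum(dur, idx)
  p[as.integer(rownames(tab))] <- tab
  probabilityTable(p, n)
}

#' Time-weighted sampled moments from spikes
#'
#' Computes \eqn{\langle z_i \rangle} (on-state occupancy) and, for the
#' requested unit pairs, \eqn{\langle z_i z_j \rangle} (fraction of time
#' both units are on) directly from spikes and refractory times, without
#' building the full state table. This is the moment estimator used for
#' high-dimensional networks, where the \code{2^n} state table is not
#' representable.
#'
#' @param spikes a [SpikeTrain-class].
#' @param tauRef refractory time(s), scalar or per unit.
#' @param window numeric \code{c(t0, t1)}, ms.
#' @param ids neuron ids of the units, in unit order.
#' @param pairs 2-column integer matrix of unit index pairs for which second
#'   moments are computed; default all pairs i < j.
#' @return list with \code{mz} and \code{mzz} (n x n, zero outside the
#'   requested pairs, means on the diagonal).
#' @export
sampledMoments <- function(spikes, tauRef, window, ids,
                           pairs = NULL) {
  n <- length(ids)
  tauRef <- rep_len(tauRef, n)
  iv <- onIntervals(spikes, tauRef, window, ids)
  len <- window[2] - window[1]
  mz <- vapply(iv, function(x) sum(x$end - x$start), numeric(1)) / len
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    colnames(pairs) <- NULL
  }
  mzz <- matrix(0, n, n)
  if (nrow(pairs)) {
    ov <- cpp_pair_overlaps(lapply(iv, `[[`, "start"),
                            lapply(iv, `[[`, "end"),
                            matrix(as.integer(pairs) - 1L, ncol = 2)) / len
    mzz[pairs] <- ov
    mzz[pairs[, 2:1, drop = FALSE]] <- ov
  }
  diag(mzz) <- mz
  list(mz = mz, mzz = mzz)
}

#' Kullback-Leibler divergence between probability tables
#'
#' \deqn{D_{KL}(p \| q) = \sum_z p(z) \ln\frac{p(z)}{q(z)}}
#' in nats, with the convention \eqn{0 \ln 0 = 0}. Requires \eqn{q(z) > 0}
#' wherever \eqn{p(z) > 0} (always true when \eqn{q} is a Boltzmann
#' target). Non-negative; zero iff \eqn{p = q}.
#'
#' @param p,q [ProbabilityTable-class] objects over the same number of RVs.
#' @return divergence in nats.
#' @export
#' @examples
#' p <- probabilityTable(c(1, 0))
#' q <- probabilityTable(c(0.5, 0.5))
#' dkl(p, q)  # ln 2
dkl <- function(p, q) {
  stopifnot(is(p, "ProbabilityTable"), is(q, "ProbabilityTable"))
  if (p@n != q@n) stopf("tables must cover the same number of RVs")
  pp <- probs(p); qq <- probs(q)
  on <- pp > 0
  if (any(qq[on] <= 0))
    stopf("q assigns zero probability to a state with p > 0; DKL undefined")
  sum(pp[on] * log(pp[on] / qq[on]))
}

#' First and second moments of a probability table
#'
#' Returns \eqn{\langle z_i \rangle} and \eqn{\langle z_i z_j \rangle} under
#' the given distribution, by summation over the explicit state table. The
#' diagonal of the second-moment matrix equals the means.
#'
#' @param p a [ProbabilityTable-class].
#' @return list with \code{mz} (length-n vector) and \code{mzz} (n x n
#'   matrix).
#' @export
#' @examples
#' tableMoments(targetJoint(randomTarget(3, seed = 1)))$mz
tableMoments <- function(p) {
  stopifnot(is(p, "ProbabilityTable"))
  Z <- stateMatrix(p@n)
  w <- probs(p)
  mz <- as.vector(crossprod(Z, w))
  mzz <- crossprod(Z, Z * w)
  list(mz = mz, mzz = (mzz + t(mzz)) / 2)
}

#' Glauber-dynamics sampler on a Boltzmann target
#'
#' Abstract single-site Gibbs sampler: per sweep, every unit is updated in
#' sequence with \eqn{p(z_i = 1 \mid z_{\setminus i}) = \sigma(b_i + \sum_j
#' W_{ij} z_j)}. Serves as the reference MCMC dynamics that the LIF network
#' approximates, and as an independent oracle for moments and joints. State
#' occupancy is recorded once per sweep after the burn-in.
#'
#' @param target a [BoltzmannTarget-class].
#' @param sweeps number of recorded sweeps.
#' @param burnin discarded initial sweeps.
#' @param seed integer seed.
#' @param init optional initial 0/1 state (default all zeros).
#' @return list with \code{p} (a [ProbabilityTable-class]; \code{NULL} for
#'   n > 16), \code{mz}, \code{mzz} and \code{sweeps}.
#' @export
#' @examples
#' g <- glauberSample(randomTarget(3, seed = 1), sweeps = 2000, seed = 7)
#' g$mz
glauberSample <- function(target, sweeps, burnin = 1000, seed = 1L,
                          init = NULL) {
  stopifnot(is(target, "BoltzmannTarget"), sweeps >= 1)
  n <- nUnits(target)
  if (is.null(init)) init <- integer(n)
  res <- withSeed(seed,
                  cpp_glauber(target@W, target@b, sweeps, burnin,
                              as.integer(init)))
  p <- if (n <= 16) probabilityTable(res$counts, n) else NULL
  list(p = p, mz = as.vector(res$mz), mzz = res$mzz, sweeps = res$kept)
}
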