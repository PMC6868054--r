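# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps independent seed streams
# (substrate, trial, noise, data, training) from perturbing each other.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %%
               2147483647) + 1L
}

# Multiplicative lognormal factors with mean 1 and coefficient of variation
# cv. cv = 0 gives exactly 1.
lognormFactors <- function(k, cv) {
  if (cv <= 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# All 2^n binary states as an n-column 0/1 matrix; unit 1 is the
# fastest-varying bit, so row i encodes state index i.
#' Enumerate binary state vectors
#'
#' Returns the \code{2^n x n} matrix of all binary states, in the row order
#' used by [ProbabilityTable-class]: row \code{i} is the state with index
#' \code{i}, i.e. \code{1 + sum(z * 2^(seq_len(n) - 1))}; unit 1 is the
#' fastest-varying bit.
#'
#' @param n number of binary random variables (<= 20).
#' @return integer matrix of 0/1 values.
#' @export
#' @examples
#' stateMatrix(2)
stateMatrix <- function(n) {
  stopifnot(n >= 1, n <= 20)
  idx <- 0:(2^n - 1)
  m <- vapply(seq_len(n), function(k) bitwAnd(idx, bitwShiftL(1L, k - 1L)) > 0,
              logical(2^n))
  storage.mode(m) <- "integer"
  matrix(m, ncol = n)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
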