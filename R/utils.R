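#' @include AllClasses.R
NULL

## Internal numerical helpers shared across modules.

## Enumeration cap: 2^20 states is the largest exact-oracle regime we allow.
.ENUM_CAP <- 20L

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## All 2^n binary patterns, one per row, column j = bit j (neuron j).
## Row k (1-based) encodes integer k-1 with neuron 1 the least-significant bit.
allPatterns <- function(n) {
  stopifnot(n >= 1, n <= .ENUM_CAP)
  S <- 2^n
  m <- matrix(0, nrow = S, ncol = n)
  idx <- 0:(S - 1)
  for (j in seq_len(n)) {
    m[, j] <- bitwAnd(bitwShiftR(idx, j - 1L), 1L)
  }
  m
}

## Integer code (0-based) of each pattern row, neuron 1 = LSB. Used to index
## enumeration tables. Safe for n <= 20.
patternCodes <- function(X) {
  n <- ncol(X)
  as.integer(X %*% 2^(0:(n - 1)))
}

## Raw activation matrix: X (T x n) %*% t(W) (n x p) - thresholds, then the
## nonlinearity. Returns T x p matrix of f_i(x_t).
activationCore <- function(X, weights, thresholds, nl) {
  U <- X %*% t(weights)
  U <- sweep(U, 2L, thresholds, "-")
  if (nl@kind == "sigmoid") {
    1 / (1 + exp(-nl@beta * U))
  } else {
    ## Heaviside with the documented boundary convention H(0) = 1
    (U >= 0) * 1
  }
}

## Collapse a raster into unique rows and normalized counts; all data-side
## expectations are weighted sums over these.
collapseRaster <- function(X) {
  codes <- patternCodes(X)
  ord <- order(codes)
  codes <- codes[ord]
  first <- !duplicated(codes)
  counts <- tabulate(cumsum(first))
  list(patterns = X[ord[first], , drop = FALSE],
       weights = counts / nrow(X),
       counts = counts)
}

## Exact two-sided Clopper-Pearson interval for k successes in N trials.
## k may be non-integer (projection means are not always counts); qbeta
## accepts continuous shape parameters. Returns c(lo, hi).
cpInterval <- function(k, N, level) {
  alpha <- 1 - level
  lo <- ifelse(k <= 0, 0, qbeta(alpha / 2, k, N - k + 1))
  hi <- ifelse(k >= N, 1, qbeta(1 - alpha / 2, k + 1, N - k))
  cbind(lo = lo, hi = hi)
}

## withSeed: evaluate expr under a local RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
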