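#' @include AllClasses.R utils.R
NULL

#' Build a random sparse projection set
#'
#' Draws the connectivity and weights of `nProj` projections over `nNeurons`
#' input neurons. Each synapse exists independently with probability
#' `indegree / nNeurons`, so the expected number of inputs per projection is
#' `indegree`; a projection that comes out with no inputs is redrawn (an
#' inputless projection is a constant and carries no information). Existing
#' synapses get weights drawn from Normal(mean 1, sd 1), signed as drawn, and
#' every threshold is set to 1. With `indegree = nNeurons` the mask is
#' all-ones (fully connected).
#'
#' @param nNeurons number of input neurons.
#' @param nProj number of projections.
#' @param indegree expected inputs per projection; must satisfy
#'   `0 < indegree <= nNeurons`.
#' @param nonlinearity a [Nonlinearity-class].
#' @param seed integer seed; construction is fully reproducible.
#' @return A [ProjectionSet-class].
#' @examples
#' P <- buildSparseProjections(50, 10, indegree = 5,
#'                             Nonlinearity("sigmoid", beta = 2), seed = 1)
#' mean(rowSums(projectionMask(P)))  # close to 5
#' @export
buildSparseProjections <- function(nNeurons, nProj, indegree, nonlinearity,
                                   seed = 1L) {
  if (indegree <= 0 || indegree > nNeurons)
    stop("'indegree' must satisfy 0 < indegree <= nNeurons")
  if (nNeurons < 1 || nProj < 1)
    stop("need at least one neuron and one projection")
  p <- indegree / nNeurons
  withSeed(seed, {
    mask <- matrix(rbinom(nProj * nNeurons, 1L, p), nrow = nProj)
    empty <- which(rowSums(mask) == 0)
    while (length(empty)) {
      mask[empty, ] <- rbinom(length(empty) * nNeurons, 1L, p)
      empty <- which(rowSums(mask) == 0)
    }
    weights <- matrix(0, nProj, nNeurons)
    nz <- mask == 1
    weights[nz] <- rnorm(sum(nz), mean = 1, sd = 1)
    ProjectionSet(mask, weights, thresholds = rep(1, nProj),
                  nonlinearity = nonlinearity)
  })
}

#' Evaluate projections on a raster
#'
#' Computes `f_i(x_t) = sigma(sum_j a_ij x_tj - theta_i)` for every time bin
#' `t` and projection `i`. Sigmoid outputs lie in (0, 1); Heaviside outputs
#' are 0/1 with the boundary convention `H(0) = 1`.
#'
#' @param P a [ProjectionSet-class].
#' @param X a [SpikeRaster-class] or 0/1 matrix with `nNeurons(P)` columns.
#' @return Numeric matrix, `nSamples x nProjections`, entries in \[0, 1\].
#' @export
projectionActivations <- function(P, X) {
  Xm <- if (is(X, "SpikeRaster")) X@data else as.matrix(X)
  if (ncol(Xm) != nNeurons(P))
    stop(sprintf("raster has %d neurons but projections expect %d",
                 ncol(Xm), nNeurons(P)))
  activationCore(Xm, P@weights, P@thresholds, P@nonlinearity)
}
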