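#' @include AllClasses.R AllGenerics.R utils.R projections.R
NULL

#' Energy of binary patterns under an RPModel
#'
#' The energy of a pattern is `E(x) = sum_i lambda_i f_i(x)`; the model
#' probability is `p(x) = exp(-E(x)) / Z`. With no projections (or all
#' multipliers zero) every pattern has energy 0 and the model is uniform.
#'
#' @param model an [RPModel-class].
#' @param x a single binary pattern (vector), a 0/1 matrix (rows = patterns),
#'   or a [SpikeRaster-class].
#' @return Numeric vector of energies, one per pattern.
#' @examples
#' nl <- Nonlinearity("heaviside")
#' P <- ProjectionSet(matrix(1, 1, 2), matrix(c(1, 1), 1, 2), 1, nl)
#' M <- RPModel(P, lambdas = 2)
#' energy(M, c(0, 0))  # 0: the projection is silent
#' energy(M, c(1, 1))  # 2
#' @export
setMethod("energy", "RPModel", function(model, x) {
  if (is(x, "SpikeRaster")) x <- x@data
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nNeurons(model))
    stop(sprintf("pattern length %d does not match %d neurons",
                 ncol(x), nNeurons(model)))
  if (nProjections(model) == 0L) return(rep(0, nrow(x)))
  F <- projectionActivations(model@projections, x)
  as.numeric(F %*% model@lambdas)
})

#' Exact distribution by enumeration
#'
#' Enumerates all `2^n` binary patterns and computes the partition function
#' `Z = sum_x exp(-E(x))` and every pattern probability exactly. This is the
#' exact oracle against which samplers and trainers are checked. Refuses
#' populations above the enumeration cap (`n > 20`); use the annealed
#' importance sampling path ([estimateLogPartitionAIS()]) there.
#'
#' @param M an [RPModel-class] with `nNeurons <= 20`.
#' @return A list with elements `Z`, `logZ`, `probs` (length `2^n`, indexed
#'   by pattern code + 1, where the code reads neuron 1 as the least
#'   significant bit), and `energies` (same indexing).
#' @examples
#' nl <- Nonlinearity("heaviside")
#' P <- ProjectionSet(matrix(1, 1, 2), matrix(c(1, 1), 1, 2), 1, nl)
#' M <- RPModel(P, lambdas = log(3))
#' enumerateDistribution(M)$Z  # 2
#' @export
enumerateDistribution <- function(M) {
  n <- nNeurons(M)
  if (n > .ENUM_CAP)
    stop(sprintf(paste("exact enumeration refused for n = %d > %d neurons",
                       "(2^n states); use the AIS estimate instead"),
                 n, .ENUM_CAP))
  X <- allPatterns(n)
  E <- energy(M, X)
  logZ <- logSumExp(-E)
  probs <- exp(-E - logZ)
  list(Z = exp(logZ), logZ = logZ, probs = probs, energies = E)
}

#' Exact mean log-likelihood of a raster
#'
#' `(1/T) sum_t [ -E(x_t) - log Z ]` in nats per sample, with `Z` computed by
#' exact enumeration. For the uniform model (no projections or all-zero
#' multipliers) this equals `-n log 2` for any raster.
#'
#' @param M an [RPModel-class] with `nNeurons <= 20`.
#' @param X a [SpikeRaster-class] or 0/1 matrix.
#' @return Mean log-likelihood in nats per sample.
#' @seealso [testLogLikelihood()] for the sampled-`Z` path at larger `n`.
#' @export
exactMeanLogLikelihood <- function(M, X) {
  if (is(X, "SpikeRaster")) X <- X@data
  n <- nNeurons(M)
  if (n > .ENUM_CAP)
    stop("population too large for exact enumeration; use testLogLikelihood(method = 'ais')")
  logZ <- enumerateDistribution(M)$logZ
  mean(-energy(M, X)) - logZ
}
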