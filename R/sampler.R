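#' @include AllClasses.R utils.R model.R
NULL

.nlParams <- function(P) {
  nl <- P@nonlinearity
  list(beta = if (nl@kind == "sigmoid") nl@beta else 0,
       heaviside = nl@kind == "heaviside")
}

#' Metropolis-Hastings sampling from an RPModel
#'
#' Runs a single-site Metropolis-Hastings chain on the model's Gibbs
#' distribution: at each step one uniformly chosen neuron's bit is proposed
#' to flip and accepted with probability `min(1, exp(E(x) - E(x')))`.
#' `burnIn` and `thin` are counted in proposed flips; the defaults
#' (`10 * n` and `n`) give one expected update per neuron between retained
#' samples. The chain is bit-reproducible given `cfg@seed`.
#'
#' A warning is emitted when the realized acceptance rate falls below 1%
#' (symptomatic of a pathological model, e.g. very large multipliers).
#'
#' @param M an [RPModel-class].
#' @param cfg a [ChainConfig-class].
#' @return A [SpikeRaster-class] with `cfg@nSamples` rows; the acceptance
#'   rate is attached as attribute `"acceptanceRate"`.
#' @examples
#' P <- buildSparseProjections(6, 4, 3, Nonlinearity("sigmoid", beta = 2),
#'                             seed = 2)
#' X <- mhSample(RPModel(P, rep(0.5, 4)), ChainConfig(1000, seed = 7))
#' colMeans(rasterMatrix(X))
#' @export
mhSample <- function(M, cfg) {
  validObject(M); validObject(cfg)
  P <- M@projections
  n <- nNeurons(P)
  burn <- if (is.na(cfg@burnIn)) 10L * n else as.integer(cfg@burnIn)
  thin <- if (is.na(cfg@thin)) n else as.integer(cfg@thin)
  init <- switch(cfg@init,
    zeros = integer(n),
    data_pattern = {
      if (length(cfg@initPattern) != n)
        stop("initPattern length does not match the model")
      as.integer(cfg@initPattern)
    },
    random = NULL)
  np <- .nlParams(P)
  res <- withSeed(cfg@seed, {
    if (is.null(init)) init <- rbinom(n, 1L, 0.5)
    cpp_mh_sample(P@weights, P@thresholds, M@lambdas, np$beta, np$heaviside,
                  init, as.integer(cfg@nSamples), burn, thin)
  })
  acc <- res$accepted / res$proposed
  if (acc < 0.01)
    warning(sprintf("MH acceptance rate %.3f%% < 1%%; chain may mix poorly",
                    100 * acc))
  out <- SpikeRaster(res$samples)
  attr(out, "acceptanceRate") <- acc
  out
}

#' Annealed-importance-sampling estimate of log Z
#'
#' Estimates the log partition function by annealing independent chains from
#' the uniform distribution (`log Z0 = n log 2`) to the model along a ladder
#' of inverse temperatures, geometric by default with `nTemps` rungs.
#' Between rungs each chain performs `sweeps` full sweeps (`n` proposed
#' flips each) at the new temperature. The estimate is
#' `n log 2 + logmeanexp(log weights)`; the standard error comes from a
#' bootstrap over chains.
#'
#' @param M an [RPModel-class].
#' @param nChains number of AIS chains (>= 2).
#' @param nTemps number of ladder rungs (>= 2; default 100).
#' @param seed integer seed.
#' @param sweeps MH sweeps per rung (default 1).
#' @param nBoot bootstrap resamples for the standard error (default 500).
#' @return A list with `logZ`, `se`, and the per-chain `logWeights`.
#' @examples
#' P <- buildSparseProjections(8, 5, 4, Nonlinearity("sigmoid", beta = 2),
#'                             seed = 3)
#' M <- RPModel(P, rep(0.8, 5))
#' ais <- estimateLogPartitionAIS(M, nChains = 50, nTemps = 30, seed = 1)
#' c(ais$logZ, enumerateDistribution(M)$logZ)
#' @export
estimateLogPartitionAIS <- function(M, nChains, nTemps = 100, seed = 1L,
                                    sweeps = 1L, nBoot = 500L) {
  validObject(M)
  if (nChains < 2 || nTemps < 2)
    stop("need nChains >= 2 and nTemps >= 2")
  P <- M@projections
  n <- nNeurons(P)
  ## geometric ladder in inverse temperature, prefixed with exactly 0
  ladder <- c(0, exp(seq(log(1e-3), 0, length.out = nTemps - 1)))
  if (any(diff(ladder) <= 0)) stop("degenerate temperature ladder")
  np <- .nlParams(P)
  logw <- withSeed(seed, {
    cpp_ais(P@weights, P@thresholds, M@lambdas, np$beta, np$heaviside,
            as.integer(nChains), ladder, as.integer(sweeps))
  })
  est <- n * log(2) + logSumExp(logw) - log(nChains)
  boot <- withSeed(seed + 1L, {
    vapply(seq_len(nBoot), function(b) {
      w <- logw[sample.int(nChains, replace = TRUE)]
      logSumExp(w) - log(nChains)
    }, numeric(1))
  })
  list(logZ = est, se = stats::sd(boot), logWeights = logw)
}
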