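#' @include AllClasses.R model.R sampler.R
NULL

#' BudgetReport: synaptic budget accounting
#'
#' @slot used total `sum_ij |a_ij|` of the evaluated projection set.
#' @slot available constraint-implied ceiling: number of synapses times
#'   `omega` (bounded), `phi` times the number of projections
#'   (`homeo_input`), `phi` times the number of input neurons
#'   (`homeo_output`), `phi` (`homeo_circuit`), `Inf` (unconstrained).
#' @slot normalizedUsed `used` in units where the initial projection set's
#'   total absolute weight equals 1.
#' @export
setClass("BudgetReport",
  representation(used = "numeric", available = "numeric",
                 normalizedUsed = "numeric")
)

setMethod("show", "BudgetReport", function(object) {
  cat(sprintf("BudgetReport: used %.4f | available %s | %.4f x initial set\n",
              object@used,
              if (is.finite(object@available))
                sprintf("%.4f", object@available) else "unbounded",
              object@normalizedUsed))
})

#' Held-out mean log-likelihood
#'
#' Mean per-sample log-probability of a raster under the model, in nats.
#' `method = "exact"` uses enumeration (requires `nNeurons <= 20`);
#' `method = "ais"` normalizes with an annealed-importance-sampling estimate
#' of `log Z` and propagates its uncertainty into the standard error.
#'
#' @param M an [RPModel-class].
#' @param X_test evaluation raster ([SpikeRaster-class] or 0/1 matrix).
#' @param method `"exact"` or `"ais"`.
#' @param nChains,nTemps,seed AIS settings (see
#'   [estimateLogPartitionAIS()]).
#' @return List with `meanLL` (nats per sample) and `se`.
#' @export
testLogLikelihood <- function(M, X_test, method = c("exact", "ais"),
                              nChains = 100, nTemps = 100, seed = 1L) {
  method <- match.arg(method)
  if (is(X_test, "SpikeRaster")) X_test <- X_test@data
  E <- energy(M, X_test)
  Tn <- nrow(X_test)
  if (method == "exact") {
    logZ <- enumerateDistribution(M)$logZ
    lp <- -E - logZ
    list(meanLL = mean(lp), se = stats::sd(lp) / sqrt(Tn))
  } else {
    ais <- estimateLogPartitionAIS(M, nChains = nChains, nTemps = nTemps,
                                   seed = seed)
    list(meanLL = mean(-E) - ais$logZ,
         se = sqrt(stats::var(E) / Tn + ais$se^2))
  }
}

#' Compare model and empirical pattern probabilities
#'
#' For each pattern, tabulates the empirical probability (count / T), the
#' model probability, and a two-sided Clopper-Pearson confidence funnel
#' around the empirical probability at level `ci`. With enumerable
#' populations (default when `nNeurons <= 12`) every pattern is listed,
#' including never-observed ones (empirical probability 0, lower funnel
#' bound 0); otherwise only observed patterns are listed and `log Z` is
#' estimated by AIS.
#'
#' @param M an [RPModel-class].
#' @param X_test evaluation raster.
#' @param ci funnel confidence level (default 0.99).
#' @param includeUnobserved list all `2^n` patterns (default `TRUE` when
#'   `nNeurons <= 12`).
#' @param seed AIS seed for the large-`n` path.
#' @return `data.frame` with columns `pattern` (bit string, neuron 1 first),
#'   `count`, `empirical_p`, `model_p`, `ci_lo`, `ci_hi`, sorted by
#'   `empirical_p` descending.
#' @export
patternProbabilityComparison <- function(M, X_test, ci = 0.99,
                                         includeUnobserved =
                                           nNeurons(M) <= 12,
                                         seed = 1L) {
  if (is(X_test, "SpikeRaster")) X_test <- X_test@data
  n <- nNeurons(M)
  Tn <- nrow(X_test)
  codes <- patternCodes(X_test)
  counts <- table(codes)
  obsCodes <- as.integer(names(counts))
  obsCounts <- as.integer(counts)
  if (n <= .ENUM_CAP) {
    dist <- enumerateDistribution(M)
    if (includeUnobserved) {
      allCodes <- 0:(2^n - 1)
      cnt <- integer(2^n)
      cnt[obsCodes + 1L] <- obsCounts
      codesOut <- allCodes; countsOut <- cnt
      modelP <- dist$probs
    } else {
      codesOut <- obsCodes; countsOut <- obsCounts
      modelP <- dist$probs[obsCodes + 1L]
    }
  } else {
    ais <- estimateLogPartitionAIS(M, nChains = 100, nTemps = 100,
                                   seed = seed)
    pats <- matrix(0, length(obsCodes), n)
    for (j in seq_len(n))
      pats[, j] <- bitwAnd(bitwShiftR(obsCodes, j - 1L), 1L)
    modelP <- exp(-energy(M, pats) - ais$logZ)
    codesOut <- obsCodes; countsOut <- obsCounts
  }
  bits <- vapply(codesOut, function(k)
    paste(bitwAnd(bitwShiftR(k, 0:(n - 1)), 1L), collapse = ""),
    character(1))
  funnel <- cpInterval(countsOut, Tn, ci)
  out <- data.frame(pattern = bits, count = countsOut,
                    empirical_p = countsOut / Tn,
                    model_p = as.numeric(modelP),
                    ci_lo = funnel[, "lo"], ci_hi = funnel[, "hi"],
                    stringsAsFactors = FALSE)
  out[order(-out$empirical_p), , drop = FALSE]
}

.sourceRaster <- function(M, source, X, chainConfig) {
  if (source == "samples" && is.null(X)) {
    if (is.null(chainConfig)) chainConfig <- ChainConfig(nSamples = 50000)
    X <- mhSample(M, chainConfig)
  }
  if (is(X, "SpikeRaster")) X <- X@data
  X
}

#' Projection firing rates
#'
#' The expectation `<f_i>` of every projection — the mean activity per time
#' bin of the corresponding intermediate-layer neuron — either exactly under
#' the model distribution or as a sample mean over a raster.
#'
#' @param M an [RPModel-class].
#' @param source `"exact"` (enumeration) or `"samples"`.
#' @param X raster for `source = "samples"`; when omitted one is drawn from
#'   the model with `chainConfig`.
#' @param chainConfig optional [ChainConfig-class] for the sampled path.
#' @return Numeric vector of rates in \[0, 1\], one per projection.
#' @export
projectionFiringRates <- function(M, source = c("exact", "samples"),
                                  X = NULL, chainConfig = NULL) {
  source <- match.arg(source)
  if (source == "exact") {
    dist <- enumerateDistribution(M)
    F <- projectionActivations(M@projections, allPatterns(nNeurons(M)))
    as.numeric(crossprod(F, dist$probs))
  } else {
    X <- .sourceRaster(M, source, X, chainConfig)
    colMeans(projectionActivations(M@projections, X))
  }
}

#' Mean pairwise correlation between projections
#'
#' Pearson correlation of the projection outputs `f_i` under the model
#' distribution (exact, via enumeration) or over a raster (sampled),
#' averaged over all unordered pairs. Zero-variance projections are
#' excluded with a message; if fewer than two projections vary, the
#' correlation is undefined and an error is raised.
#'
#' @inheritParams projectionFiringRates
#' @return Mean pairwise Pearson correlation (scalar).
#' @export
projectionCorrelations <- function(M, source = c("exact", "samples"),
                                   X = NULL, chainConfig = NULL) {
  source <- match.arg(source)
  if (nProjections(M) < 2)
    stop("need at least two projections for pairwise correlations")
  if (source == "exact") {
    dist <- enumerateDistribution(M)
    F <- projectionActivations(M@projections, allPatterns(nNeurons(M)))
    mu <- as.numeric(crossprod(F, dist$probs))
    Fc <- sweep(F, 2L, mu, "-")
    C <- crossprod(Fc * dist$probs, Fc)          # covariance matrix
    v <- diag(C)
  } else {
    X <- .sourceRaster(M, source, X, chainConfig)
    F <- projectionActivations(M@projections, X)
    C <- stats::cov(F) * (nrow(F) - 1) / nrow(F)
    v <- diag(C)
  }
  keep <- v > 1e-14
  if (sum(keep) < 2)
    stop("all (or all but one) projections are constant; correlation undefined")
  if (any(!keep))
    message(sprintf("excluding %d zero-variance projection(s)", sum(!keep)))
  C <- C[keep, keep, drop = FALSE]; v <- v[keep]
  R <- C / sqrt(outer(v, v))
  mean(R[upper.tri(R)])
}

#' Rotation angles between two projection sets
#'
#' The angle, in degrees, between each projection's weight vector in `P0`
#' and the corresponding row of `P1`:
#' `alpha_i = acos(a0_i . a1_i / (|a0_i| |a1_i|))`, in \[0, 180\]. Summarizes
#' how far reshaping moved each projection's hyperplane. Masked-out entries
#' are zeros in both rows and contribute nothing.
#'
#' @param P0,P1 [ProjectionSet-class] objects of identical shape and mask.
#' @return Numeric vector of angles in degrees.
#' @export
rotationAngles <- function(P0, P1) {
  if (!all(dim(P0@mask) == dim(P1@mask)) || !all(P0@mask == P1@mask))
    stop("projection sets must share shape and mask")
  W0 <- P0@weights; W1 <- P1@weights
  n0 <- sqrt(rowSums(W0^2)); n1 <- sqrt(rowSums(W1^2))
  if (any(n0 == 0) || any(n1 == 0))
    stop("zero-norm projection row; angle undefined")
  cosv <- rowSums(W0 * W1) / (n0 * n1)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Synaptic budget accounting
#'
#' Total absolute synaptic weight used by a projection set, the ceiling the
#' constraint makes available, and the used budget in units of the initial
#' projection set's total absolute weight (so the untouched initial set has
#' normalized budget 1). For `homeo_input` models the used budget equals
#' the available one exactly.
#'
#' @param P the evaluated [ProjectionSet-class].
#' @param P_initial the initial [ProjectionSet-class] defining the unit.
#' @param constraint a [ConstraintSpec-class].
#' @return A [BudgetReport-class].
#' @export
synapticBudget <- function(P, P_initial,
                           constraint = ConstraintSpec("none")) {
  if (!all(dim(P@mask) == dim(P_initial@mask)))
    stop("projection sets must have the same shape")
  used <- sum(abs(P@weights))
  avail <- switch(constraint@kind,
    none = Inf,
    bounded = sum(P@mask) * constraint@omega,
    homeo_input = constraint@phi * nrow(P@mask),
    homeo_output = constraint@phi * ncol(P@mask),
    homeo_circuit = constraint@phi)
  unit <- sum(abs(P_initial@weights))
  new("BudgetReport", used = used, available = avail,
      normalizedUsed = used / unit)
}

#' Empirical CDF of relative firing-rate changes
#'
#' Distribution function of `|r_final - r_initial| / r_initial` across
#' projections, summarizing how much reshaping moved each projection
#' neuron's firing rate. Projections with zero initial rate are excluded
#' (their relative change is undefined) with a message; the count is
#' attached as attribute `"excluded"`.
#'
#' @param ratesInitial,ratesFinal numeric vectors of per-projection rates.
#' @return A [stats::ecdf()] step function on \[0, Inf).
#' @export
firingRateChangeCdf <- function(ratesInitial, ratesFinal) {
  if (length(ratesInitial) != length(ratesFinal))
    stop("rate vectors must have equal length")
  keep <- ratesInitial > 0
  if (any(!keep))
    message(sprintf("excluding %d projection(s) with zero initial rate",
                    sum(!keep)))
  if (!any(keep)) stop("no projections with positive initial rate")
  rel <- abs(ratesFinal[keep] - ratesInitial[keep]) / ratesInitial[keep]
  out <- stats::ecdf(rel)
  attr(out, "excluded") <- sum(!keep)
  out
}
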