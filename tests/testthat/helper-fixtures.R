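# Shared fixture builders. Everything is generated in code under fixed seeds.

sigmoid2 <- function() Nonlinearity("sigmoid", beta = 2)

# The closed-form two-neuron case: one Heaviside projection a = (1, 1),
# theta = 1, H(0) = 1, so f = 1 on 3 of the 4 patterns. At lambda = log 3
# the projection marginal is exactly 1/2 and Z = 2.
closedFormModel <- function(lambda = log(3)) {
  P <- ProjectionSet(matrix(1, 1, 2), matrix(c(1, 1), 1, 2), 1,
                     Nonlinearity("heaviside"))
  RPModel(P, lambda)
}

# A raster whose single-projection marginal under closedFormModel is exactly
# 1/2: half all-zero rows (f = 0), half all-one rows (f = 1).
closedFormRaster <- function(nPerHalf = 50000) {
  SpikeRaster(rbind(matrix(0, nPerHalf, 2), matrix(1, nPerHalf, 2)))
}

# Random small model with moderate multipliers; enumeration-friendly.
randomModel <- function(n = 8, nProj = 10, indegree = 4, beta = 2,
                        seed = 1, lambdaRange = c(0.3, 1.2)) {
  P <- buildSparseProjections(n, nProj, indegree,
                              Nonlinearity("sigmoid", beta = beta),
                              seed = seed)
  lam <- withr::with_seed(seed + 500, runif(nProj, lambdaRange[1],
                                            lambdaRange[2]))
  RPModel(P, lam)
}

# Bernoulli(p) raster, independent neurons.
coinRaster <- function(nSamples, n, p = 0.5, seed = 1) {
  withr::with_seed(seed,
    SpikeRaster(matrix(rbinom(nSamples * n, 1, p), ncol = n)))
}

# All 2^n binary patterns; column 1 is the least-significant bit, matching
# the package's pattern-code convention.
allPatternsFor <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# Batch-means standard error of MCMC averages: columns of `x` are per-sample
# statistics from one chain; consecutive blocks absorb the autocorrelation.
blockSE <- function(x, nBlocks = 50) {
  x <- as.matrix(x)
  idx <- cut(seq_len(nrow(x)), nBlocks, labels = FALSE)
  bm <- apply(x, 2, function(col) tapply(col, idx, mean))
  apply(bm, 2, sd) / sqrt(nBlocks)
}

expect_within_se <- function(est, truth, se, k = 3) {
  expect_true(all(abs(est - truth) <= k * se + 1e-12),
              label = sprintf("estimate within %g SE of truth", k))
}
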