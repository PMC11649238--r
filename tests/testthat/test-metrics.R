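test_that("held-out likelihood: uniform value, AIS agreement, truth dominance", {
  P <- buildSparseProjections(10, 6, 4, sigmoid2(), seed = 1)
  M0 <- RPModel(P, rep(0, 6))
  X <- coinRaster(500, 10, 0.5, seed = 2)
  expect_equal(testLogLikelihood(M0, X)$meanLL, -10 * log(2))

  M <- randomModel(n = 12, nProj = 14, indegree = 5, seed = 3)
  Xs <- mhSample(M, ChainConfig(nSamples = 5000, burnIn = 2000,
                                thin = 36, seed = 4))
  ex <- testLogLikelihood(M, Xs, method = "exact")
  ai <- testLogLikelihood(M, Xs, method = "ais", nChains = 120,
                          nTemps = 80, seed = 5)
  expect_within_se(ai$meanLL, ex$meanLL, ai$se)

  # the generating model beats a fitted competitor on its own samples
  Mfit <- RPModel(projections(M), lambdas(M) * 0.5)
  exFit <- testLogLikelihood(Mfit, Xs, method = "exact")
  expect_gte(ex$meanLL, exFit$meanLL - 2 * (ex$se + exFit$se))
})

test_that("pattern-probability table: funnels, sorting, unobserved patterns", {
  M <- randomModel(n = 6, nProj = 8, indegree = 3, seed = 11)
  Xs <- mhSample(M, ChainConfig(nSamples = 20000, burnIn = 1000,
                                thin = 12, seed = 12))
  tab <- patternProbabilityComparison(M, Xs)
  expect_equal(nrow(tab), 2^6)
  expect_true(all(diff(tab$empirical_p) <= 0))
  expect_equal(sum(tab$empirical_p), 1)
  unseen <- tab[tab$count == 0, ]
  expect_true(all(unseen$ci_lo == 0))
  # a well-specified model lands in its own 99% funnel for well-sampled
  # patterns
  seen <- tab[tab$count >= 10, ]
  expect_gte(mean(seen$model_p >= seen$ci_lo & seen$model_p <= seen$ci_hi),
             0.95)
  # the empirical distribution itself is always inside its funnel
  emp <- tab; emp$model_p <- emp$empirical_p
  expect_true(all(emp$model_p >= emp$ci_lo & emp$model_p <= emp$ci_hi))
})

test_that("projection firing rates: closed form, flat-sigmoid limit, sampling", {
  # uniform two-neuron model, Heaviside projection: 3 of 4 patterns fire
  M <- closedFormModel(lambda = 0)
  expect_equal(projectionFiringRates(M, "exact"), 0.75)
  # beta -> 0 pushes every rate to 1/2
  P <- buildSparseProjections(6, 5, 3, Nonlinearity("sigmoid", beta = 1e-9),
                              seed = 21)
  Mflat <- RPModel(P, runif(5))
  expect_equal(projectionFiringRates(Mflat, "exact"), rep(0.5, 5),
               tolerance = 1e-6)
  # sample estimate matches enumeration
  M2 <- randomModel(n = 8, nProj = 10, seed = 22)
  truth <- projectionFiringRates(M2, "exact")
  X <- mhSample(M2, ChainConfig(nSamples = 30000, burnIn = 2000,
                                thin = 24, seed = 23))
  est <- projectionFiringRates(M2, "samples", X = X)
  F <- projectionActivations(projections(M2), X)
  se <- sqrt(apply(F, 2, var) / nrow(rasterMatrix(X)))
  expect_within_se(est, truth, se)
})

test_that("projection correlations: duplicates, independence, sampling", {
  # duplicated projection rows correlate perfectly
  P <- buildSparseProjections(6, 2, 3, sigmoid2(), seed = 31)
  W <- projectionWeights(P)
  Pdup <- ProjectionSet(rbind(projectionMask(P)[1, ], projectionMask(P)[1, ]),
                        rbind(W[1, ], W[1, ]), c(1, 1), sigmoid2())
  expect_equal(projectionCorrelations(RPModel(Pdup, c(1, 1)), "exact"), 1)
  # disjoint inputs under an independent (uniform) model: zero correlation
  mask <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0))
  Pdis <- ProjectionSet(mask, mask * 0.8, c(1, 1), sigmoid2())
  expect_equal(projectionCorrelations(RPModel(Pdis, c(0, 0)), "exact"), 0,
               tolerance = 1e-12)
  # sample agreement with the exact value
  M <- randomModel(n = 8, nProj = 8, seed = 32)
  truth <- projectionCorrelations(M, "exact")
  X <- mhSample(M, ChainConfig(nSamples = 30000, burnIn = 2000,
                               thin = 24, seed = 33))
  expect_equal(projectionCorrelations(M, "samples", X = X), truth,
               tolerance = 0.02)
})

test_that("rotation angles: identity, orthogonality, scale invariance, range", {
  P <- buildSparseProjections(8, 6, 4, sigmoid2(), seed = 41)
  expect_equal(rotationAngles(P, P), rep(0, 6), tolerance = 1e-5)
  m <- matrix(c(1, 1), 1, 2)
  P0 <- ProjectionSet(m, matrix(c(1, 0), 1), 1, sigmoid2())
  P1 <- ProjectionSet(m, matrix(c(0, 1), 1), 1, sigmoid2())
  expect_equal(rotationAngles(P0, P1), 90)
  Pscaled <- ProjectionSet(projectionMask(P), 2.5 * projectionWeights(P),
                           thresholds(P), sigmoid2())
  expect_equal(rotationAngles(P, Pscaled), rep(0, 6), tolerance = 1e-5)
  Pflip <- ProjectionSet(projectionMask(P), -projectionWeights(P),
                         thresholds(P), sigmoid2())
  expect_equal(rotationAngles(P, Pflip), rep(180, 6), tolerance = 1e-5)
  expect_error(rotationAngles(P, buildSparseProjections(8, 6, 4, sigmoid2(),
                                                        seed = 42)), "mask")
})

test_that("synaptic budget accounting matches the constraint formulas", {
  P <- buildSparseProjections(10, 150, 5, sigmoid2(), seed = 51)
  rep0 <- synapticBudget(P, P)
  expect_equal(rep0@normalizedUsed, 1)
  expect_equal(rep0@used, sum(abs(projectionWeights(P))))
  # homeostatic input: available = phi * nProj
  cs <- ConstraintSpec("homeo_input", phi = 2)
  W <- applyConstraint(projectionWeights(P), projectionMask(P), cs)
  Pc <- ProjectionSet(projectionMask(P), W, thresholds(P), sigmoid2())
  repH <- synapticBudget(Pc, P, cs)
  expect_equal(repH@available, 300)
  expect_equal(repH@used, repH@available, tolerance = 1e-10)
  # bounded: available = number of synapses * omega
  csB <- ConstraintSpec("bounded", omega = 0.5)
  repB <- synapticBudget(P, P, csB)
  expect_equal(repB@available, sum(projectionMask(P)) * 0.5)
})

test_that("firing-rate change CDF handles steps, exclusions, and limits", {
  cdf <- firingRateChangeCdf(c(0.2, 0.3), c(0.2, 0.3))
  expect_equal(cdf(0), 1)      # all mass at zero change
  cdf2 <- firingRateChangeCdf(0.4, 0.2)   # halved: one mass point at 0.5
  expect_equal(cdf2(0.49), 0)
  expect_equal(cdf2(0.5), 1)
  expect_message(cdf3 <- firingRateChangeCdf(c(0, 0.2), c(0.1, 0.3)),
                 "zero initial rate")
  expect_equal(attr(cdf3, "excluded"), 1)
  expect_equal(cdf3(1e6), 1)
  expect_error(firingRateChangeCdf(0.1, c(0.1, 0.2)), "equal length")
})

test_that("reshaped models fire less and decorrelate relative to multiplier-trained models", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(8, 10, 4, sig, seed = 61)
  d <- sampleSyntheticRaster(gt, 20000, 4000, seed = 62)
  # projection-rich regime: the firing-rate and decorrelation effects of
  # reshaping strengthen with the number of projections
  P0 <- buildSparseProjections(8, 24, 4, sig, seed = 63)
  M <- RPModel(P0, rep(1, 24))
  fitL <- trainLambdas(M, d$train, OptimizerConfig(learningRate = 0.1,
                                                   maxIters = 1000))
  fitR <- trainReshape(M, d$train, OptimizerConfig(learningRate = 0.05,
                                                   maxIters = 600))
  expect_lt(mean(projectionFiringRates(fitR$model, "exact")),
            mean(projectionFiringRates(fitL$model, "exact")))
  expect_lt(projectionCorrelations(fitR$model, "exact"),
            projectionCorrelations(fitL$model, "exact"))
})
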