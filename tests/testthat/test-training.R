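test_that("multiplier gradient has the marginal-matching fixed point", {
  M <- randomModel(n = 6, nProj = 5, seed = 1)
  m <- runif(5)
  expect_equal(lambdaGradient(M, m, m), rep(0, 5))
  expect_error(lambdaGradient(M, m[1:3], m), "per projection")
  # ascent check: the analytic gradient of the exact LL equals model - data
  X <- coinRaster(300, 6, 0.3, seed = 2)
  g <- logLikGradients(M, X)
  h <- 1e-6
  for (i in c(1, 4)) {
    bump <- function(d) {
      lam <- lambdas(M); lam[i] <- lam[i] + d
      exactMeanLogLikelihood(RPModel(projections(M), lam), X)
    }
    expect_equal((bump(h) - bump(-h)) / (2 * h), g$lambda[i],
                 tolerance = 1e-6)
  }
})

test_that("the two-neuron fixed point recovers lambda = log 3", {
  M0 <- closedFormModel(lambda = 0)
  X <- closedFormRaster(50000)   # projection marginal exactly 1/2
  fit <- trainLambdas(M0, X, OptimizerConfig(learningRate = 0.3,
                                             maxIters = 3000,
                                             ciLevel = 0.05))
  expect_equal(lambdas(fit$model), log(3), tolerance = 0.01)
  expect_true(all(fit$report@converged))
})

test_that("training on fair-coin data leaves the model uniform", {
  # when data marginals equal the uniform model's marginals, the maximum
  # entropy solution is the uniform distribution itself
  n <- 6
  X <- SpikeRaster(allPatternsFor(n))   # exactly uniform empirical marginals
  M <- randomModel(n = n, nProj = 8, seed = 3)
  M0 <- RPModel(projections(M), rep(0, 8))
  fit <- trainLambdas(M0, X, OptimizerConfig(learningRate = 0.1,
                                             maxIters = 2000))
  expect_equal(exactMeanLogLikelihood(fit$model, X), -n * log(2),
               tolerance = 0.01)
})

test_that("Clopper-Pearson convergence matches binom.test and its coverage is calibrated", {
  expect_true(clopperPearsonConverged(50, 100, 0.5))
  expect_false(clopperPearsonConverged(0, 100, 0.5))
  expect_error(clopperPearsonConverged(5, 0, 0.5), "positive")
  # cross-check interval endpoints against stats::binom.test
  bt <- binom.test(37, 120, conf.level = 0.6827)$conf.int
  expect_true(clopperPearsonConverged(37, 120, bt[1] + 1e-9))
  expect_true(clopperPearsonConverged(37, 120, bt[2] - 1e-9))
  expect_false(clopperPearsonConverged(37, 120, bt[1] - 1e-4))
  expect_false(clopperPearsonConverged(37, 120, bt[2] + 1e-4))
  # coverage: the true p should be accepted at the nominal rate
  k <- withr::with_seed(42, rbinom(10000, 1000, 0.3))
  cover <- mean(clopperPearsonConverged(k, 1000, 0.3, ciLevel = 0.6827))
  expect_equal(cover, 0.683, tolerance = 0.02)
})

test_that("reshape gradient fixed point, lambda scaling, and Heaviside rejection", {
  M <- randomModel(n = 6, nProj = 4, seed = 5)
  stats <- list(dSigmaDa = matrix(runif(24), 4, 6))
  expect_equal(reshapeGradient(M, stats, stats), matrix(0, 4, 6))
  # lambda_i = 0 kills the row update
  M2 <- RPModel(projections(M), c(0, 1, 1, 1))
  g <- reshapeGradient(M2, list(dSigmaDa = matrix(0, 4, 6)), stats)
  expect_equal(g[1, ], rep(0, 6))
  Mh <- closedFormModel()
  expect_error(reshapeGradient(Mh, stats, stats), "Heaviside")
  expect_error(trainReshape(Mh, closedFormRaster(10),
                            OptimizerConfig(maxIters = 1)), "Heaviside")
})

test_that("all gradients agree with finite differences under every constraint", {
  # seed chosen so every neuron has at least one outgoing synapse (the
  # homeo_output surface requires it)
  M <- randomModel(n = 6, nProj = 4, indegree = 3, seed = 13)
  X <- coinRaster(200, 6, 0.25, seed = 12)
  mask <- projectionMask(projections(M))
  specs <- list(ConstraintSpec("none"),
                ConstraintSpec("bounded", omega = 3),
                ConstraintSpec("homeo_input", phi = 2),
                ConstraintSpec("homeo_output", phi = 2),
                ConstraintSpec("homeo_circuit", phi = 8))
  At <- projectionWeights(projections(M))
  h <- 1e-6
  for (cs in specs) {
    g <- logLikGradients(M, X, cs, A_tilde = At)
    llOf <- function(A) {
      W <- applyConstraint(A, mask, cs)
      P <- ProjectionSet(mask, W, thresholds(projections(M)),
                         nonlinearity(projections(M)))
      exactMeanLogLikelihood(RPModel(P, lambdas(M)), X)
    }
    ones <- which(mask == 1)
    idx <- ones[c(1L, ceiling(length(ones) / 2), length(ones))]
    for (k in idx) {
      Ap <- At; Ap[k] <- Ap[k] + h
      Am <- At; Am[k] <- Am[k] - h
      expect_equal((llOf(Ap) - llOf(Am)) / (2 * h), g$weights[k],
                   tolerance = 1e-5, label = paste("FD", cs@kind))
    }
  }
})

test_that("applyConstraint enforces each surface and is idempotent on it", {
  m <- matrix(c(1, 1, 0), 1)
  expect_equal(applyConstraint(matrix(c(2, -2, 0), 1), m,
                               ConstraintSpec("homeo_input", phi = 2)),
               matrix(c(1, -1, 0), 1))
  b <- ConstraintSpec("bounded", omega = 1)
  expect_equal(applyConstraint(matrix(c(3, -0.4, 0), 1), m, b),
               matrix(c(1, -0.4, 0), 1))
  # already on the surface: unchanged
  A <- matrix(c(1.2, -0.8, 0), 1)
  expect_equal(applyConstraint(A, m, ConstraintSpec("homeo_input", phi = 2)),
               A)
  expect_equal(applyConstraint(A, m, ConstraintSpec("none")), A)
  expect_error(applyConstraint(matrix(0, 1, 3), m,
                               ConstraintSpec("homeo_input", phi = 1)),
               "degenerate")
  # homeo_output and homeo_circuit surfaces
  A2 <- matrix(c(1, 2, -1, 3), 2)
  m2 <- matrix(1, 2, 2)
  o <- applyConstraint(A2, m2, ConstraintSpec("homeo_output", phi = 4))
  expect_equal(colSums(abs(o)), c(4, 4))
  cst <- applyConstraint(A2, m2, ConstraintSpec("homeo_circuit", phi = 3))
  expect_equal(sum(abs(cst)), 3)
})

test_that("reshaping improves the training likelihood and respects contracts", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(8, 10, 4, sig, seed = 31)
  d <- sampleSyntheticRaster(gt, 15000, 4000, seed = 32)
  P0 <- buildSparseProjections(8, 10, 4, sig, seed = 33)
  M <- RPModel(P0, rep(1, 10))
  ll0 <- exactMeanLogLikelihood(M, d$train)
  fit <- trainReshape(M, d$train, OptimizerConfig(learningRate = 0.05,
                                                  maxIters = 400))
  expect_gt(exactMeanLogLikelihood(fit$model, d$train), ll0)
  # lambda and mask untouched; zero weights stay zero
  expect_equal(lambdas(fit$model), rep(1, 10))
  expect_equal(projectionMask(projections(fit$model)), projectionMask(P0))
  W <- projectionWeights(projections(fit$model))
  expect_true(all(W[projectionMask(P0) == 0] == 0))
  # training LL trajectory is recorded and ends higher than it starts
  tr <- fit$report@llTrajectory
  expect_equal(length(tr), fit$report@iterationsUsed)
  expect_gt(tr[length(tr)], tr[1])
  # zero iterations: identity
  fit0 <- trainReshape(M, d$train, OptimizerConfig(maxIters = 0))
  expect_equal(projectionWeights(projections(fit0$model)),
               projectionWeights(P0))
})

test_that("homeostatic constraints hold exactly at every logged step", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(8, 10, 4, sig, seed = 41)
  d <- sampleSyntheticRaster(gt, 10000, 2000, seed = 42)
  P0 <- buildSparseProjections(8, 10, 4, sig, seed = 43)
  M <- RPModel(P0, rep(1, 10))
  # step the trainer one iteration at a time so every intermediate weight
  # matrix is inspected
  cs <- ConstraintSpec("homeo_input", phi = 1)
  cur <- M
  for (k in 1:15) {
    fit <- trainReshape(cur, d$train,
                        OptimizerConfig(learningRate = 0.05, maxIters = 1),
                        cs)
    W <- projectionWeights(projections(fit$model))
    expect_equal(rowSums(abs(W)), rep(1, 10), tolerance = 1e-10)
    cur <- fit$model
  }
  # bounded: ceiling respected over a full run
  fb <- trainReshape(M, d$train,
                     OptimizerConfig(learningRate = 0.05, maxIters = 120),
                     ConstraintSpec("bounded", omega = 0.3))
  expect_lte(max(abs(projectionWeights(projections(fb$model)))), 0.3)
})

test_that("joint training degenerates to each single-mode trainer", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(7, 8, 3, sig, seed = 51)
  d <- sampleSyntheticRaster(gt, 8000, 2000, seed = 52)
  P0 <- buildSparseProjections(7, 8, 3, sig, seed = 53)
  M <- RPModel(P0, rep(1, 8))
  # lambda step zero reproduces pure reshaping
  fB <- trainBackprop(M, d$train,
                      OptimizerConfig(learningRate = 0.04, maxIters = 60,
                                      lambdaLearningRate = 0))
  fR <- trainReshape(M, d$train,
                     OptimizerConfig(learningRate = 0.04, maxIters = 60))
  expect_equal(fB$report@llTrajectory, fR$report@llTrajectory,
               tolerance = 1e-12)
  # reshape step zero reproduces pure multiplier training
  fB2 <- trainBackprop(M, d$train,
                       OptimizerConfig(learningRate = 0, maxIters = 60,
                                       lambdaLearningRate = 0.1))
  fL <- trainLambdas(M, d$train,
                     OptimizerConfig(learningRate = 0.1, maxIters = 60,
                                     ciLevel = 1e-6))
  len <- min(length(fB2$report@llTrajectory), length(fL$report@llTrajectory))
  expect_equal(fB2$report@llTrajectory[1:len],
               fL$report@llTrajectory[1:len], tolerance = 1e-12)
})

test_that("multiplier training recovers a ground-truth model's likelihood", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(8, 6, 4, sig, seed = 61)
  d <- sampleSyntheticRaster(gt, 60000, 15000, seed = 62)
  # fit lambdas on the true projections, starting from zero
  M0 <- RPModel(projections(gt), rep(0, nProjections(gt)))
  fit <- trainLambdas(M0, d$train, OptimizerConfig(learningRate = 0.1,
                                                   maxIters = 2500))
  llFit <- exactMeanLogLikelihood(fit$model, d$test)
  llTrue <- exactMeanLogLikelihood(gt, d$test)
  expect_gt(llFit, llTrue - 0.05)
  # fitted marginals inside the 1-SD Clopper-Pearson band of the data
  F <- projectionActivations(projections(gt), d$train)
  expect_true(all(clopperPearsonConverged(colSums(F), nrow(rasterMatrix(d$train)),
                                          fit$report@finalMarginals)))
})

test_that("multiplier training is monotone with exact expectations", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(6, 6, 3, sig, seed = 71)
  d <- sampleSyntheticRaster(gt, 10000, 2000, seed = 72)
  M0 <- RPModel(buildSparseProjections(6, 8, 3, sig, seed = 73), rep(0, 8))
  fit <- trainLambdas(M0, d$train,
                      OptimizerConfig(algorithm = "momentum", momentum = 0,
                                      learningRate = 0.5, maxIters = 300,
                                      ciLevel = 1e-6))
  tr <- fit$report@llTrajectory
  expect_true(all(diff(tr) > -1e-12))
})

test_that("MCMC-expectation training approaches the exact-expectation fit", {
  sig <- sigmoid2()
  gt <- makeGroundTruthModel(8, 8, 4, sig, seed = 81)
  d <- sampleSyntheticRaster(gt, 20000, 4000, seed = 82)
  M0 <- RPModel(buildSparseProjections(8, 8, 4, sig, seed = 83), rep(0, 8))
  fitE <- trainLambdas(M0, d$train, OptimizerConfig(learningRate = 0.1,
                                                    maxIters = 800))
  cfg <- OptimizerConfig(learningRate = 0.1, maxIters = 800,
                         expectationSource = "mcmc",
                         chainConfig = ChainConfig(nSamples = 1500, seed = 5),
                         seed = 9)
  fitM <- trainLambdas(M0, d$train, cfg)
  expect_equal(exactMeanLogLikelihood(fitM$model, d$test),
               exactMeanLogLikelihood(fitE$model, d$test), tolerance = 0.05)
})
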