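#' @include AllClasses.R training.R metrics.R synthetic.R
NULL

## Experiment drivers: reproducible multi-seed comparisons mirroring the
## result classes of the reshaped-projection study at desk scale. Each
## returns one tidy data.frame row per seed (x condition). All randomness
## derives from `seed`.

## derived seeds stay inside the 32-bit integer range whatever the master is
.seedBase <- function(seed) as.integer((as.numeric(seed) * 1000) %% 2^30)

.deskData <- function(s, seed, nNeurons, nProjGen, indegree, nl,
                      nTrain, nTest) {
  base <- .seedBase(seed)
  gt <- makeGroundTruthModel(nNeurons, nProjGen, indegree, nl,
                             seed = base + s)
  sampleSyntheticRaster(gt, nTrain, nTest, seed = base + 500L + s)
}

#' Compare multiplier training, reshaping, and joint training
#'
#' For each seed: synthetic data are drawn from a fresh ground-truth model;
#' one set of initial sparse projections is shared by a multiplier-trained
#' model (multipliers fitted, projections fixed), a reshaped model
#' (projections fitted, multipliers fixed at 1), and a jointly trained
#' model. Exact train and test log-likelihoods are reported for each.
#'
#' @param nSeeds number of independent repetitions.
#' @param nNeurons,nProj,indegree geometry (defaults 10 neurons, 12
#'   projections, in-degree 5).
#' @param beta sigmoid slope (default 2).
#' @param nTrain,nTest raster sizes (default 20000 / 5000).
#' @param maxIters reshape iteration cap (default 600).
#' @param seed master seed.
#' @return data.frame with per-seed train/test log-likelihoods
#'   (`trainLambda`, `trainReshape`, `trainBackprop`, `testLambda`, ...).
#' @export
runReshapeComparison <- function(nSeeds = 20, nNeurons = 10, nProj = 12,
                                 indegree = 5, beta = 2, nTrain = 20000,
                                 nTest = 5000, maxIters = 600, seed = 1L) {
  nl <- Nonlinearity("sigmoid", beta = beta)
  out <- lapply(seq_len(nSeeds), function(s) {
    d <- .deskData(s, seed, nNeurons, nProj, indegree, nl, nTrain, nTest)
    P0 <- buildSparseProjections(nNeurons, nProj, indegree, nl,
                                 seed = .seedBase(seed) + 700L + s)
    M <- RPModel(P0, rep(1, nProj))
    fL <- trainLambdas(M, d$train,
                       OptimizerConfig(learningRate = 0.1, maxIters = 1000))
    fR <- trainReshape(M, d$train,
                       OptimizerConfig(learningRate = 0.05,
                                       maxIters = maxIters))
    fB <- trainBackprop(M, d$train,
                        OptimizerConfig(learningRate = 0.05,
                                        lambdaLearningRate = 0.05,
                                        maxIters = maxIters))
    data.frame(seed = s,
               trainLambda = exactMeanLogLikelihood(fL$model, d$train),
               trainReshape = exactMeanLogLikelihood(fR$model, d$train),
               trainBackprop = exactMeanLogLikelihood(fB$model, d$train),
               testLambda = exactMeanLogLikelihood(fL$model, d$test),
               testReshape = exactMeanLogLikelihood(fR$model, d$test),
               testBackprop = exactMeanLogLikelihood(fB$model, d$test))
  })
  do.call(rbind, out)
}

#' Homeostatic versus bounded reshaping at matched available budget
#'
#' For each seed, one initial projection set is reshaped twice under the
#' same available synaptic budget: once with homeostatic input
#' normalization (`phi = budget / nProj`) and once with a per-synapse
#' ceiling (`omega = budget / nSynapses`). The budget is
#' `budgetFraction` of the initial set's total absolute weight — the
#' scarce regime by default.
#'
#' @inheritParams runReshapeComparison
#' @param budgetFraction available budget as a fraction of the initial
#'   set's total absolute weight (default 0.35).
#' @return data.frame with per-seed held-out log-likelihoods `testHomeo`
#'   and `testBounded` and the shared `budget`.
#' @export
runBudgetComparison <- function(nSeeds = 20, nNeurons = 10, nProj = 12,
                                indegree = 5, beta = 2,
                                budgetFraction = 0.35, nTrain = 20000,
                                nTest = 5000, maxIters = 600, seed = 1L) {
  nl <- Nonlinearity("sigmoid", beta = beta)
  out <- lapply(seq_len(nSeeds), function(s) {
    d <- .deskData(s, seed, nNeurons, nProj, indegree, nl, nTrain, nTest)
    P0 <- buildSparseProjections(nNeurons, nProj, indegree, nl,
                                 seed = .seedBase(seed) + 700L + s)
    M <- RPModel(P0, rep(1, nProj))
    B <- budgetFraction * sum(abs(projectionWeights(P0)))
    cfg <- OptimizerConfig(learningRate = 0.05, maxIters = maxIters)
    fh <- trainReshape(M, d$train, cfg,
                       ConstraintSpec("homeo_input", phi = B / nProj))
    fb <- trainReshape(M, d$train, cfg,
                       ConstraintSpec("bounded",
                                      omega = B / sum(projectionMask(P0))))
    data.frame(seed = s, budget = B,
               testHomeo = exactMeanLogLikelihood(fh$model, d$test),
               testBounded = exactMeanLogLikelihood(fb$model, d$test))
  })
  do.call(rbind, out)
}

#' Firing-rate homeostasis across normalization strengths
#'
#' Reshapes the same initial projections under homeostatic input
#' normalization at several budgets `phi` and records each projection
#' ensemble's mean firing rate (over the training data) before and after
#' reshaping, plus its dispersion after. A sharper sigmoid (default slope
#' 4) and a projection-rich geometry are used so the normalization
#' strength spreads the initial rates widely — the regime in which the
#' homeostatic convergence of rates is expressed.
#'
#' @inheritParams runReshapeComparison
#' @param phis homeostatic budgets to compare (default 3, 8, 20).
#' @return data.frame with one row per seed x phi: `initMeanRate`,
#'   `finalMeanRate`, `finalSdRate`, `testLL`.
#' @export
runRateHomeostasis <- function(nSeeds = 5, phis = c(3, 8, 20),
                               nNeurons = 10, nProj = 30, indegree = 5,
                               beta = 4, nTrain = 20000, nTest = 5000,
                               maxIters = 1000, seed = 1L) {
  nl <- Nonlinearity("sigmoid", beta = beta)
  out <- lapply(seq_len(nSeeds), function(s) {
    d <- .deskData(s, seed, nNeurons, 12, indegree, nl, nTrain, nTest)
    P0 <- buildSparseProjections(nNeurons, nProj, indegree, nl,
                                 seed = .seedBase(seed) + 700L + s)
    M <- RPModel(P0, rep(1, nProj))
    cfg <- OptimizerConfig(learningRate = 0.05, maxIters = maxIters)
    do.call(rbind, lapply(phis, function(phi) {
      cs <- ConstraintSpec("homeo_input", phi = phi)
      W0 <- applyConstraint(projectionWeights(P0), projectionMask(P0), cs)
      P0c <- ProjectionSet(projectionMask(P0), W0, thresholds(P0), nl)
      r0 <- colMeans(projectionActivations(P0c, d$train))
      fit <- trainReshape(M, d$train, cfg, cs)
      r1 <- colMeans(projectionActivations(projections(fit$model), d$train))
      data.frame(seed = s, phi = phi, initMeanRate = mean(r0),
                 finalMeanRate = mean(r1), finalSdRate = stats::sd(r1),
                 testLL = exactMeanLogLikelihood(fit$model, d$test))
    }))
  })
  do.call(rbind, out)
}

#' Reshaping from true, random, and full connectivity
#'
#' Follows the known-connectivity synthetic design: a sparse RP model is
#' first fitted (multiplier training) to a warm-up raster and used as the
#' data generator, so its connectivity is the ground truth. Homeostatic
#' reshaping is then run from three initial masks — the generator's own,
#' an independent random sparse draw, and full connectivity — with fresh
#' Normal(1, 1) weights on each, at the same per-projection budget `phi`.
#'
#' @inheritParams runReshapeComparison
#' @param phi homeostatic input budget (default 1.4; scarce regime).
#' @return data.frame with per-seed held-out log-likelihoods `testTrue`,
#'   `testRandom`, `testFull`.
#' @export
runConnectivityComparison <- function(nSeeds = 10, nNeurons = 10,
                                      nProj = 30, indegree = 5, beta = 2,
                                      phi = 1.4, nTrain = 20000,
                                      nTest = 5000, maxIters = 600,
                                      seed = 1L) {
  nl <- Nonlinearity("sigmoid", beta = beta)
  out <- lapply(seq_len(nSeeds), function(s) {
    warm <- .deskData(s, seed, nNeurons, 12, indegree, nl, nTrain, 100)
    Pg <- buildSparseProjections(nNeurons, nProj, indegree, nl,
                                 seed = .seedBase(seed) + 600L + s)
    gen <- trainLambdas(RPModel(Pg, rep(0, nProj)), warm$train,
                        OptimizerConfig(learningRate = 0.1,
                                        maxIters = 800))$model
    d <- sampleSyntheticRaster(gen, nTrain, nTest,
                               seed = .seedBase(seed) + 650L + s)
    drawOn <- function(mask, sub) {
      W <- matrix(0, nrow(mask), ncol(mask))
      nz <- mask == 1
      W[nz] <- withSeed(.seedBase(seed) + sub + s, rnorm(sum(nz), 1, 1))
      ProjectionSet(mask, W, rep(1, nrow(mask)), nl)
    }
    Pt <- drawOn(projectionMask(Pg), 700L)
    Pr <- buildSparseProjections(nNeurons, nProj, indegree, nl,
                                 seed = .seedBase(seed) + 750L + s)
    Pf <- drawOn(matrix(1, nProj, nNeurons), 800L)
    cfg <- OptimizerConfig(learningRate = 0.05, maxIters = maxIters)
    cs <- ConstraintSpec("homeo_input", phi = phi)
    llOf <- function(P)
      exactMeanLogLikelihood(trainReshape(RPModel(P, rep(1, nProj)),
                                          d$train, cfg, cs)$model, d$test)
    data.frame(seed = s, testTrue = llOf(Pt), testRandom = llOf(Pr),
               testFull = llOf(Pf))
  })
  do.call(rbind, out)
}
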