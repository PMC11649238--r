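#' @include AllClasses.R utils.R model.R sampler.R constraints.R
NULL

#' Ascent direction for the Lagrange multipliers
#'
#' Under the sign convention `p(x) = exp(-sum_i lambda_i f_i(x)) / Z`, the
#' derivative of the mean training log-likelihood with respect to
#' `lambda_i` is `<f_i>_model - <f_i>_data`. This function returns that
#' ascent direction: its fixed point is exact matching of the projection
#' marginals, and small steps along it increase the training likelihood
#' (the problem is convex in the multipliers).
#'
#' @param M an [RPModel-class] (used for dimension checks).
#' @param dataMarginals empirical projection means `<f_i>_data`, in \[0,1\].
#' @param modelMarginals model projection means `<f_i>_model`, in \[0,1\].
#' @return Numeric vector of length `nProjections(M)`.
#' @export
lambdaGradient <- function(M, dataMarginals, modelMarginals) {
  p <- nProjections(M)
  if (length(dataMarginals) != p || length(modelMarginals) != p)
    stop("marginal vectors must have one entry per projection")
  as.numeric(modelMarginals) - as.numeric(dataMarginals)
}

#' Clopper-Pearson convergence check
#'
#' A projection is considered converged when the model's marginal lies
#' inside the exact (Clopper-Pearson) two-sided binomial confidence interval
#' around the empirical marginal. The default level 0.6827 reads "one
#' standard deviation" as the Gaussian two-sided 1-SD coverage.
#'
#' All arguments are vectorized over projections. `successCount` may be
#' non-integer (sigmoid projection means are not counts); the Beta-quantile
#' form of the interval accepts continuous arguments.
#'
#' @param successCount observed successes `k` (possibly fractional).
#' @param nObs number of observations `N` (> 0).
#' @param modelMarginal the model marginal to test.
#' @param ciLevel two-sided confidence level in (0, 1).
#' @return Logical vector: `TRUE` where the model marginal is inside the
#'   interval.
#' @examples
#' clopperPearsonConverged(50, 100, 0.5)   # TRUE
#' clopperPearsonConverged(0, 100, 0.5)    # FALSE
#' @export
clopperPearsonConverged <- function(successCount, nObs, modelMarginal,
                                    ciLevel = 0.6827) {
  if (any(nObs <= 0)) stop("nObs must be positive")
  if (any(successCount < 0) || any(successCount > nObs))
    stop("successCount must lie in [0, nObs]")
  ci <- cpInterval(successCount, nObs, ciLevel)
  modelMarginal >= ci[, "lo"] & modelMarginal <= ci[, "hi"]
}

## Expectation statistics of a projection set over a weighted pattern set:
## marginals <f_i>, and (sigmoid only, when needWeights) the matrices
## <dsigma/da_ij> and vector <dsigma/dtheta_i>.
.expectStats <- function(P, patterns, w, needWeights) {
  F <- activationCore(patterns, P@weights, P@thresholds, P@nonlinearity)
  marg <- as.numeric(crossprod(F, w))
  out <- list(marginals = marg)
  if (needWeights) {
    beta <- P@nonlinearity@beta
    D <- beta * F * (1 - F)          # dsigma/du per (pattern, projection)
    Dw <- D * w
    out$dSigmaDa <- crossprod(Dw, patterns) * P@mask   # p x n
    out$dSigmaDtheta <- -colSums(Dw)
  }
  out
}

#' Ascent direction for reshaping the projection weights
#'
#' Implements the reshape rule: the update for synapse `a_ij` is
#' `lambda_i * (<dsigma/da_ij>_model - <dsigma/da_ij>_data)`, which is the
#' exact gradient of the mean training log-likelihood with respect to the
#' weights under the `exp(-E)/Z` convention, with
#' `dsigma/da_ij = beta * sigma(u_i)(1 - sigma(u_i)) * x_j`. Only synapses
#' present in the mask are updated. When a constraint reparameterization is
#' active the gradient is pulled back to the unconstrained parameters
#' `A_tilde` by the chain rule (subgradient of `|.|` at 0 taken as 0; for
#' `bounded` and `none` the pullback is the identity — the bounded mode does
#' projected ascent).
#'
#' Reshaping requires a sigmoid nonlinearity: the Heaviside step has zero
#' derivative almost everywhere and is rejected.
#'
#' @param M an [RPModel-class] with sigmoid nonlinearity.
#' @param dataStats,modelStats lists with element `dSigmaDa`
#'   (`nProj x nNeurons` matrix of averaged `dsigma/da_ij`), as produced
#'   internally from a data batch / the model distribution.
#' @param constraint a [ConstraintSpec-class].
#' @param A_tilde unconstrained parameter matrix the gradient is taken with
#'   respect to; defaults to the model's current weights.
#' @return Weight-update matrix (`nProj x nNeurons`), zero outside the mask.
#' @export
reshapeGradient <- function(M, dataStats, modelStats,
                            constraint = ConstraintSpec("none"),
                            A_tilde = NULL) {
  P <- M@projections
  if (P@nonlinearity@kind == "heaviside")
    stop("reshaping is not supported for the Heaviside nonlinearity (zero gradient almost everywhere)")
  if (is.null(A_tilde)) A_tilde <- P@weights
  gA <- M@lambdas * (modelStats$dSigmaDa - dataStats$dSigmaDa)
  constraintChainRule(gA, A_tilde, P@mask, constraint)
}

#' Exact log-likelihood gradients (enumeration-based)
#'
#' Computes, by exact enumeration, the gradient of the mean training
#' log-likelihood with respect to the multipliers, the unconstrained weight
#' parameters (through the constraint reparameterization), and the
#' thresholds. Intended for diagnostics and finite-difference verification
#' on small populations.
#'
#' @param M an [RPModel-class] with `nNeurons <= 20`.
#' @param X a [SpikeRaster-class] or 0/1 matrix of training patterns.
#' @param constraint a [ConstraintSpec-class]; the model's weights must lie
#'   on its constraint surface (they are interpreted as
#'   `applyConstraint(A_tilde, ...)` evaluated at `A_tilde`).
#' @param A_tilde unconstrained parameters; defaults to a matrix whose
#'   constrained image equals the model's weights.
#' @return List with `lambda`, `weights` (w.r.t. `A_tilde`), `thresholds`.
#' @export
logLikGradients <- function(M, X, constraint = ConstraintSpec("none"),
                            A_tilde = NULL) {
  P <- M@projections
  if (is(X, "SpikeRaster")) X <- X@data
  if (is.null(A_tilde)) A_tilde <- P@weights
  W <- applyConstraint(A_tilde, P@mask, constraint)
  Puse <- P; Puse@weights <- W
  Muse <- M; Muse@projections <- Puse
  sig <- P@nonlinearity@kind == "sigmoid"
  XP <- allPatterns(nNeurons(M))
  dist <- enumerateDistribution(Muse)
  ms <- .expectStats(Puse, XP, dist$probs, needWeights = sig)
  dd <- collapseRaster(X)
  ds <- .expectStats(Puse, dd$patterns, dd$weights, needWeights = sig)
  out <- list(lambda = ms$marginals - ds$marginals)
  if (sig) {
    gA <- M@lambdas * (ms$dSigmaDa - ds$dSigmaDa)
    out$weights <- constraintChainRule(gA, A_tilde, P@mask, constraint)
    out$thresholds <- M@lambdas * (ms$dSigmaDtheta - ds$dSigmaDtheta)
  }
  out
}

## ---------------------------------------------------------------------------
## Core trainer. All three public modes are specializations, so the
## degeneration contracts (backprop with one step size zero reproduces the
## single-mode trajectories) hold by construction.
.trainCore <- function(M, X, cfg, constraint, updateLambda, updateWeights) {
  t0 <- proc.time()[["elapsed"]]
  validObject(M); validObject(cfg); validObject(constraint)
  if (is(X, "SpikeRaster")) X <- X@data
  P <- M@projections
  n <- nNeurons(P); p <- nProjections(P)
  if (ncol(X) != n) stop("raster does not match the model's neuron count")
  sig <- P@nonlinearity@kind == "sigmoid"
  if (updateWeights && !sig)
    stop("reshaping is not supported for the Heaviside nonlinearity (zero gradient almost everywhere)")
  exact <- cfg@expectationSource == "exact"
  if (exact && n > .ENUM_CAP)
    stop("exact expectations require nNeurons <= 20; use expectationSource = 'mcmc'")

  lam <- M@lambdas
  A_tilde <- P@weights
  theta <- P@thresholds
  curP <- P
  curP@weights <- applyConstraint(A_tilde, P@mask, constraint)

  dd <- collapseRaster(X)
  Tn <- nrow(X)
  dataStats <- .expectStats(curP, dd$patterns, dd$weights,
                            needWeights = updateWeights)

  if (exact) {
    XP <- allPatterns(n)
    FpCache <- NULL
    FdCache <- NULL
    if (!updateWeights) {   # projections fixed: activations never change
      FpCache <- activationCore(XP, curP@weights, theta, P@nonlinearity)
      FdCache <- activationCore(dd$patterns, curP@weights, theta,
                                P@nonlinearity)
    }
  } else {
    ## persistent chains initialized from random data rows
    nChains <- as.integer(cfg@chainConfig@nSamples)
    thin <- if (is.na(cfg@chainConfig@thin)) n else
      as.integer(cfg@chainConfig@thin)
    states <- withSeed(cfg@seed, {
      idx <- sample.int(Tn, nChains, replace = TRUE)
      st <- X[idx, , drop = FALSE]
      storage.mode(st) <- "integer"
      st
    })
    rngSeed <- as.integer(cfg@seed) + 1L
  }

  ## optimizer state
  zL <- numeric(p); zA <- matrix(0, p, n); zT <- numeric(p)
  mL <- zL; vL <- zL; mA <- zA; vA <- zA; mT <- zT; vT <- zT
  lrW <- cfg@learningRate
  lrL <- if (updateLambda && updateWeights && !is.na(cfg@lambdaLearningRate))
    cfg@lambdaLearningRate else cfg@learningRate

  adamStep <- function(m, v, g, t) {
    m <- cfg@beta1 * m + (1 - cfg@beta1) * g
    v <- cfg@beta2 * v + (1 - cfg@beta2) * g^2
    mhat <- m / (1 - cfg@beta1^t); vhat <- v / (1 - cfg@beta2^t)
    list(m = m, v = v, step = mhat / (sqrt(vhat) + cfg@epsilon))
  }

  llTraj <- numeric(0)
  converged <- rep(FALSE, p)
  modelMarg <- rep(NA_real_, p)
  iters <- 0L

  for (t in seq_len(cfg@maxIters)) {
    iters <- t
    if (updateWeights) {
      curP@weights <- applyConstraint(A_tilde, P@mask, constraint)
      dataStats <- .expectStats(curP, dd$patterns, dd$weights, TRUE)
    }
    if (exact) {
      Fp <- if (is.null(FpCache))
        activationCore(XP, curP@weights, theta, P@nonlinearity) else FpCache
      E <- as.numeric(Fp %*% lam)
      logZ <- logSumExp(-E)
      probs <- exp(-E - logZ)
      modelStats <- list(marginals = as.numeric(crossprod(Fp, probs)))
      if (updateWeights) {
        beta <- P@nonlinearity@beta
        Dw <- (beta * Fp * (1 - Fp)) * probs
        modelStats$dSigmaDa <- crossprod(Dw, XP) * P@mask
        modelStats$dSigmaDtheta <- -colSums(Dw)
      }
      Fd <- if (is.null(FdCache))
        activationCore(dd$patterns, curP@weights, theta, P@nonlinearity) else
        FdCache
      llTraj <- c(llTraj,
                  sum(dd$weights * (-as.numeric(Fd %*% lam))) - logZ)
    } else {
      states <- withSeed(rngSeed + t, {
        np <- .nlParams(curP)
        cpp_advance_states(curP@weights, theta, lam, np$beta, np$heaviside,
                           states, thin)
      })
      modelStats <- .expectStats(curP, states, rep(1 / nrow(states),
                                                   nrow(states)),
                                 needWeights = updateWeights)
      llTraj <- c(llTraj, NA_real_)
    }
    modelMarg <- modelStats$marginals

    gL <- modelStats$marginals - dataStats$marginals
    if (any(!is.finite(gL))) stop("non-finite multiplier gradient; aborting")

    cpOK <- clopperPearsonConverged(dataStats$marginals * Tn, Tn,
                                    modelStats$marginals, cfg@ciLevel)
    gradOK <- rep(TRUE, p)

    if (updateWeights) {
      gA <- lam * (modelStats$dSigmaDa - dataStats$dSigmaDa)
      gAt <- constraintChainRule(gA, A_tilde, P@mask, constraint)
      if (any(!is.finite(gAt))) stop("non-finite reshape gradient; aborting")
      gradOK <- apply(abs(gAt), 1L, max) < cfg@gradTol
      if (cfg@tuneThresholds) {
        gT <- lam * (modelStats$dSigmaDtheta - dataStats$dSigmaDtheta)
        gradOK <- gradOK & abs(gT) < cfg@gradTol
      }
    }
    converged <- (!updateLambda | cpOK) & (!updateWeights | gradOK)
    if (all(converged)) break

    ## parameter updates (ascent)
    if (updateLambda && lrL > 0) {
      if (cfg@algorithm == "adam") {
        st <- adamStep(mL, vL, gL, t); mL <- st$m; vL <- st$v
        lam <- lam + lrL * st$step
      } else {
        mL <- cfg@momentum * mL + gL
        lam <- lam + lrL * mL
      }
    }
    if (updateWeights && lrW > 0) {
      if (cfg@algorithm == "adam") {
        st <- adamStep(mA, vA, gAt, t); mA <- st$m; vA <- st$v
        A_tilde <- A_tilde + lrW * st$step * P@mask
      } else {
        mA <- cfg@momentum * mA + gAt
        A_tilde <- A_tilde + lrW * mA * P@mask
      }
      if (constraint@kind == "bounded")
        A_tilde <- pmin(pmax(A_tilde, -constraint@omega), constraint@omega)
      if (cfg@tuneThresholds) {
        if (cfg@algorithm == "adam") {
          st <- adamStep(mT, vT, gT, t); mT <- st$m; vT <- st$v
          theta <- theta + lrW * st$step
        } else {
          mT <- cfg@momentum * mT + gT
          theta <- theta + lrW * mT
        }
      }
    }
  }

  curP@weights <- applyConstraint(A_tilde, P@mask, constraint)
  curP@thresholds <- theta
  outM <- RPModel(curP, lam)
  report <- new("FitReport", llTrajectory = llTraj, converged = converged,
                finalMarginals = as.numeric(modelMarg),
                iterationsUsed = as.numeric(iters),
                budgetUsed = sum(abs(curP@weights)),
                elapsed = proc.time()[["elapsed"]] - t0)
  list(model = outM, report = report)
}

#' Train the Lagrange multipliers of an RPModel
#'
#' Maximizes the training log-likelihood over the multipliers with the
#' projections held fixed (the convex, maximum-entropy formulation). Model
#' expectations come from exact enumeration or a persistent MH chain;
#' training stops when every projection's model marginal passes the
#' Clopper-Pearson convergence rule or `maxIters` is reached.
#'
#' @param M an [RPModel-class]; its current multipliers are the
#'   initialization.
#' @param X training raster ([SpikeRaster-class] or 0/1 matrix).
#' @param cfg an [OptimizerConfig-class].
#' @return List with elements `model` (the fitted [RPModel-class]) and
#'   `report` (a [FitReport-class]).
#' @export
trainLambdas <- function(M, X, cfg = OptimizerConfig()) {
  .trainCore(M, X, cfg, ConstraintSpec("none"),
             updateLambda = TRUE, updateWeights = FALSE)
}

#' Reshape the projections of an RPModel
#'
#' Maximizes the training log-likelihood over the nonzero projection weights
#' (and optionally the thresholds, `cfg@tuneThresholds`) with the
#' multipliers held fixed, under a synaptic constraint that is maintained
#' exactly after every iteration through its reparameterization. The
#' problem is non-convex; a local optimum is accepted. Requires a sigmoid
#' nonlinearity.
#'
#' With `maxIters = 0` the model is returned unchanged apart from the
#' initial projection of its weights onto the constraint surface.
#'
#' @inheritParams trainLambdas
#' @param constraint a [ConstraintSpec-class] (default unconstrained).
#' @return List with `model` and `report`, as [trainLambdas()].
#' @export
trainReshape <- function(M, X, cfg = OptimizerConfig(),
                         constraint = ConstraintSpec("none")) {
  .trainCore(M, X, cfg, constraint,
             updateLambda = FALSE, updateWeights = TRUE)
}

#' Jointly train multipliers and projections (backpropagation-style)
#'
#' Applies the multiplier update and the reshape update in the same gradient
#' step, like backpropagation through the two layers of the circuit
#' implementation. `cfg@learningRate` scales the weight step and
#' `cfg@lambdaLearningRate` (default: same) the multiplier step; setting
#' either to zero degenerates exactly to the other single-mode trainer.
#'
#' @inheritParams trainReshape
#' @return List with `model` and `report`, as [trainLambdas()].
#' @export
trainBackprop <- function(M, X, cfg = OptimizerConfig(),
                          constraint = ConstraintSpec("none")) {
  .trainCore(M, X, cfg, constraint,
             updateLambda = TRUE, updateWeights = TRUE)
}
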