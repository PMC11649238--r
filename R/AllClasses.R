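#' @useDynLib reshapeRP, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats qbeta rnorm runif rbinom sd cor var quantile setNames
#' @importFrom utils head modifyList
#' @importFrom tools md5sum
NULL

## Central S4 classes. All binary activity is stored as plain numeric/integer
## matrices with entries in {0, 1}; rows are time bins, columns are neurons.

#' SpikeRaster: binned binary population activity
#'
#' A matrix of 0/1 spiking activity, rows = time bins, columns = neurons,
#' with the bin width carried as metadata (purely descriptive; no operation
#' depends on it).
#'
#' @slot data numeric matrix with entries in \{0,1\}; `nSamples x nNeurons`.
#' @slot binWidth bin duration in milliseconds (default 20).
#'
#' @export
setClass("SpikeRaster",
  representation(data = "matrix", binWidth = "numeric"),
  prototype(binWidth = 20)
)

setValidity("SpikeRaster", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be a numeric matrix")
  if (nrow(d) < 1L || ncol(d) < 1L)
    return("raster needs at least one time bin and one neuron")
  if (anyNA(d) || !all(d == 0 | d == 1))
    return("raster entries must all be 0 or 1")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    return("'binWidth' must be a single positive duration")
  TRUE
})

#' Construct a SpikeRaster
#'
#' @param data 0/1 matrix, rows = time bins, columns = neurons.
#' @param binWidth bin width in milliseconds (metadata only).
#' @return A [SpikeRaster-class] object.
#' @examples
#' X <- SpikeRaster(matrix(rbinom(60, 1, 0.2), nrow = 20))
#' nNeurons(X)
#' @export
SpikeRaster <- function(data, binWidth = 20) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("SpikeRaster", data = data, binWidth = binWidth)
}

#' Nonlinearity of a projection
#'
#' The pointwise nonlinearity applied to each projection's summed, thresholded
#' input: either a Heaviside step (with the convention H(0) = 1) or a logistic
#' sigmoid `1 / (1 + exp(-beta * u))` whose slope is set by `beta`. As
#' `beta -> Inf` the sigmoid converges to the Heaviside step at every nonzero
#' argument; as `beta -> 0` every projection output tends to the constant 1/2
#' and the model degenerates to an independent (uniform-energy) model.
#'
#' @slot kind `"heaviside"` or `"sigmoid"`.
#' @slot beta positive slope; `NA` for Heaviside.
#' @export
setClass("Nonlinearity",
  representation(kind = "character", beta = "numeric")
)

setValidity("Nonlinearity", function(object) {
  if (!object@kind %in% c("heaviside", "sigmoid"))
    return("kind must be 'heaviside' or 'sigmoid'")
  if (object@kind == "sigmoid" &&
      (length(object@beta) != 1L || is.na(object@beta) || object@beta <= 0))
    return("sigmoid nonlinearity requires a single positive 'beta'")
  TRUE
})

#' Construct a Nonlinearity
#'
#' @param kind `"sigmoid"` or `"heaviside"`.
#' @param beta sigmoid slope; required (positive) when `kind = "sigmoid"`.
#' @return A [Nonlinearity-class] object.
#' @examples
#' Nonlinearity("sigmoid", beta = 2)
#' Nonlinearity("heaviside")
#' @export
Nonlinearity <- function(kind = c("sigmoid", "heaviside"), beta = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "heaviside") beta <- NA_real_
  new("Nonlinearity", kind = kind, beta = as.numeric(beta))
}

#' ProjectionSet: sparse synaptic connectivity of the intermediate layer
#'
#' Each of the `nProj` projections is a nonlinear function
#' `f_i(x) = sigma(sum_j a_ij x_j - theta_i)` of the binary population
#' pattern `x`. The binary `mask` records which synapses exist; `weights`
#' holds the coefficients `a_ij` (exactly zero wherever the mask is zero).
#'
#' @slot mask binary matrix, `nProj x nNeurons`; 1 = synapse present.
#' @slot weights real matrix, same shape; `a_ij`.
#' @slot thresholds numeric vector `theta_i`, length `nProj`.
#' @slot nonlinearity a [Nonlinearity-class].
#' @export
setClass("ProjectionSet",
  representation(mask = "matrix", weights = "matrix",
                 thresholds = "numeric", nonlinearity = "Nonlinearity")
)

setValidity("ProjectionSet", function(object) {
  m <- object@mask; w <- object@weights
  if (!all(dim(m) == dim(w)))
    return("mask and weights must have identical dimensions")
  if (nrow(m) < 1L || ncol(m) < 1L)
    return("need at least one projection and one neuron")
  if (!all(m == 0 | m == 1)) return("mask entries must be 0 or 1")
  if (any(rowSums(m) == 0)) return("every projection needs at least one input")
  if (any(w[m == 0] != 0)) return("weights must be exactly 0 outside the mask")
  if (length(object@thresholds) != nrow(m))
    return("thresholds must have one entry per projection")
  if (anyNA(w) || any(!is.finite(w))) return("weights must be finite")
  TRUE
})

#' Construct a ProjectionSet
#'
#' @param mask binary `nProj x nNeurons` matrix.
#' @param weights real matrix, zero outside the mask.
#' @param thresholds numeric vector of projection thresholds.
#' @param nonlinearity a [Nonlinearity-class].
#' @return A [ProjectionSet-class] object.
#' @seealso [buildSparseProjections()] for the random sparse constructor.
#' @export
ProjectionSet <- function(mask, weights, thresholds, nonlinearity) {
  mask <- as.matrix(mask); storage.mode(mask) <- "double"
  weights <- as.matrix(weights); storage.mode(weights) <- "double"
  new("ProjectionSet", mask = mask, weights = weights,
      thresholds = as.numeric(thresholds), nonlinearity = nonlinearity)
}

#' RPModel: a random-projection maximum-entropy model
#'
#' The model assigns each binary population pattern `x` the Gibbs probability
#' `p(x) = exp(-E(x)) / Z` with energy `E(x) = sum_i lambda_i f_i(x)`, where
#' the `f_i` are the projections of a [ProjectionSet-class] and the
#' `lambda_i` are Lagrange multipliers. It is the maximum-entropy
#' distribution consistent with the observed projection means.
#'
#' @slot projections a [ProjectionSet-class].
#' @slot lambdas numeric vector, one multiplier per projection.
#' @export
setClass("RPModel",
  representation(projections = "ProjectionSet", lambdas = "numeric")
)

setValidity("RPModel", function(object) {
  if (length(object@lambdas) != nrow(object@projections@mask))
    return("lambdas must have one entry per projection")
  if (anyNA(object@lambdas) || any(!is.finite(object@lambdas)))
    return("lambdas must be finite")
  TRUE
})

#' Construct an RPModel
#'
#' @param projections a [ProjectionSet-class].
#' @param lambdas numeric vector of Lagrange multipliers (default all 1, the
#'   convention used when reshaping projections with fixed multipliers).
#' @return An [RPModel-class] object.
#' @export
RPModel <- function(projections, lambdas = rep(1, nProjections(projections))) {
  new("RPModel", projections = projections, lambdas = as.numeric(lambdas))
}

#' ConstraintSpec: synaptic constraint governing reshaping
#'
#' Five regimes for the projection weights during training:
#' \describe{
#'   \item{none}{unconstrained reshaping.}
#'   \item{bounded}{per-synapse ceiling `|a_ij| <= omega`.}
#'   \item{homeo_input}{homeostatic normalization of each projection's
#'     incoming weights, `sum_j |a_ij| = phi` for every projection `i`.}
#'   \item{homeo_output}{normalization of each input neuron's outgoing
#'     weights, `sum_i |a_ij| = phi` for every neuron `j`.}
#'   \item{homeo_circuit}{circuit-wide normalization,
#'     `sum_ij |a_ij| = phi`.}
#' }
#'
#' @slot kind one of the five regime names.
#' @slot omega synapse ceiling (bounded only), else `NA`.
#' @slot phi synaptic budget (homeostatic kinds only), else `NA`.
#' @export
setClass("ConstraintSpec",
  representation(kind = "character", omega = "numeric", phi = "numeric")
)

setValidity("ConstraintSpec", function(object) {
  kinds <- c("none", "bounded", "homeo_input", "homeo_output", "homeo_circuit")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (object@kind == "bounded") {
    if (is.na(object@omega) || object@omega <= 0)
      return("bounded constraint requires positive 'omega'")
    if (!is.na(object@phi)) return("'phi' must be NA for bounded constraint")
  } else if (grepl("^homeo", object@kind)) {
    if (is.na(object@phi) || object@phi <= 0)
      return("homeostatic constraint requires positive 'phi'")
    if (!is.na(object@omega)) return("'omega' must be NA for homeostatic kinds")
  } else {
    if (!is.na(object@omega) || !is.na(object@phi))
      return("'none' takes neither omega nor phi")
  }
  TRUE
})

#' Construct a ConstraintSpec
#'
#' @param kind `"none"`, `"bounded"`, `"homeo_input"`, `"homeo_output"` or
#'   `"homeo_circuit"`.
#' @param omega per-synapse ceiling (bounded only).
#' @param phi synaptic budget (homeostatic kinds only).
#' @return A [ConstraintSpec-class] object.
#' @examples
#' ConstraintSpec("homeo_input", phi = 2)
#' ConstraintSpec("bounded", omega = 0.5)
#' @export
ConstraintSpec <- function(kind = c("none", "bounded", "homeo_input",
                                    "homeo_output", "homeo_circuit"),
                           omega = NA_real_, phi = NA_real_) {
  kind <- match.arg(kind)
  new("ConstraintSpec", kind = kind, omega = as.numeric(omega),
      phi = as.numeric(phi))
}

#' ChainConfig: Metropolis-Hastings chain settings
#'
#' Single-neuron flip proposals; `burnIn` and `thin` count proposed flips.
#' When left `NA` they default at sampling time to `10 * nNeurons` and
#' `nNeurons` flips respectively (one expected update per neuron between
#' retained samples).
#'
#' @slot nSamples number of retained samples.
#' @slot burnIn flips discarded before retention (`NA` = `10 * n`).
#' @slot thin flips between retained samples (`NA` = `n`).
#' @slot seed integer seed; the chain is bit-reproducible given the seed.
#' @slot init `"random"`, `"zeros"`, or `"data_pattern"` (requires
#'   `initPattern`).
#' @slot initPattern optional starting pattern for `init = "data_pattern"`.
#' @export
setClass("ChainConfig",
  representation(nSamples = "numeric", burnIn = "numeric", thin = "numeric",
                 seed = "numeric", init = "character",
                 initPattern = "numeric")
)

setValidity("ChainConfig", function(object) {
  if (object@nSamples < 1) return("nSamples must be >= 1")
  if (!is.na(object@thin) && object@thin < 1) return("thin must be >= 1")
  if (!is.na(object@burnIn) && object@burnIn < 0) return("burnIn must be >= 0")
  if (!object@init %in% c("random", "zeros", "data_pattern"))
    return("init must be 'random', 'zeros' or 'data_pattern'")
  if (object@init == "data_pattern" && length(object@initPattern) == 0)
    return("init = 'data_pattern' requires initPattern")
  TRUE
})

#' Construct a ChainConfig
#'
#' @param nSamples retained samples.
#' @param burnIn discarded initial flips (`NA` = `10 * nNeurons`).
#' @param thin flips between retained samples (`NA` = `nNeurons`).
#' @param seed integer seed.
#' @param init chain initialization: `"random"`, `"zeros"`, `"data_pattern"`.
#' @param initPattern starting pattern when `init = "data_pattern"`.
#' @return A [ChainConfig-class] object.
#' @export
ChainConfig <- function(nSamples, burnIn = NA_real_, thin = NA_real_,
                        seed = 1L, init = "random",
                        initPattern = numeric(0)) {
  new("ChainConfig", nSamples = as.numeric(nSamples),
      burnIn = as.numeric(burnIn), thin = as.numeric(thin),
      seed = as.numeric(seed), init = init,
      initPattern = as.numeric(initPattern))
}

#' OptimizerConfig: gradient-training settings
#'
#' Shared by multiplier training, reshaping, and joint training. Model
#' expectations come either from exact enumeration (small populations) or
#' from a persistent Metropolis-Hastings chain refreshed every iteration.
#' Convergence of multiplier training follows the Clopper-Pearson rule: stop
#' once every projection's model marginal lies inside the two-sided exact
#' binomial interval (level `ciLevel`, default the Gaussian one-standard-
#' deviation coverage 0.6827) around its empirical marginal.
#'
#' @slot algorithm `"adam"` or `"momentum"`.
#' @slot learningRate positive step size.
#' @slot momentum momentum coefficient (momentum algorithm).
#' @slot beta1,beta2,epsilon ADAM moment decay rates and stabilizer.
#' @slot maxIters iteration cap.
#' @slot expectationSource `"exact"` or `"mcmc"`.
#' @slot chainConfig [ChainConfig-class] used when `expectationSource`
#'   is `"mcmc"`.
#' @slot ciLevel Clopper-Pearson convergence level.
#' @slot tuneThresholds also tune the projection thresholds during reshaping.
#' @slot lambdaLearningRate step size for the multiplier part of joint
#'   training (`NA` = `learningRate`).
#' @slot gradTol infinity-norm gradient tolerance declaring a projection's
#'   reshape converged.
#' @slot seed integer seed for stochastic expectation estimators.
#' @export
setClass("OptimizerConfig",
  representation(algorithm = "character", learningRate = "numeric",
                 momentum = "numeric", beta1 = "numeric", beta2 = "numeric",
                 epsilon = "numeric", maxIters = "numeric",
                 expectationSource = "character", chainConfig = "ChainConfig",
                 ciLevel = "numeric", tuneThresholds = "logical",
                 lambdaLearningRate = "numeric", gradTol = "numeric",
                 seed = "numeric")
)

setValidity("OptimizerConfig", function(object) {
  if (!object@algorithm %in% c("adam", "momentum"))
    return("algorithm must be 'adam' or 'momentum'")
  if (object@learningRate < 0) return("learningRate must be >= 0")
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    return("ciLevel must be in (0, 1)")
  if (object@maxIters < 0) return("maxIters must be >= 0")
  if (!object@expectationSource %in% c("exact", "mcmc"))
    return("expectationSource must be 'exact' or 'mcmc'")
  TRUE
})

#' Construct an OptimizerConfig
#'
#' @param algorithm `"adam"` (default) or `"momentum"`.
#' @param learningRate step size (default 0.05).
#' @param momentum momentum coefficient (default 0.9).
#' @param beta1,beta2,epsilon ADAM hyperparameters.
#' @param maxIters iteration cap (default 500).
#' @param expectationSource `"exact"` (default) or `"mcmc"`.
#' @param chainConfig chain settings for `"mcmc"` expectations.
#' @param ciLevel Clopper-Pearson convergence level (default 0.6827).
#' @param tuneThresholds tune thresholds too during reshaping (default FALSE).
#' @param lambdaLearningRate multiplier step size in joint training
#'   (`NA` = `learningRate`).
#' @param gradTol reshape gradient tolerance (default 1e-6).
#' @param seed integer seed.
#' @return An [OptimizerConfig-class] object.
#' @export
OptimizerConfig <- function(algorithm = c("adam", "momentum"),
                            learningRate = 0.05, momentum = 0.9,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            maxIters = 500,
                            expectationSource = c("exact", "mcmc"),
                            chainConfig = ChainConfig(nSamples = 2000),
                            ciLevel = 0.6827, tuneThresholds = FALSE,
                            lambdaLearningRate = NA_real_, gradTol = 1e-6,
                            seed = 1L) {
  new("OptimizerConfig", algorithm = match.arg(algorithm),
      learningRate = learningRate, momentum = momentum, beta1 = beta1,
      beta2 = beta2, epsilon = epsilon, maxIters = as.numeric(maxIters),
      expectationSource = match.arg(expectationSource),
      chainConfig = chainConfig, ciLevel = ciLevel,
      tuneThresholds = tuneThresholds,
      lambdaLearningRate = as.numeric(lambdaLearningRate),
      gradTol = gradTol, seed = as.numeric(seed))
}

#' FitReport: training trajectory and convergence diagnostics
#'
#' @slot llTrajectory per-iteration mean training log-likelihood in nats per
#'   sample (exact expectations) or `NA` (MCMC expectations).
#' @slot converged logical, one flag per projection (Clopper-Pearson rule for
#'   multiplier training; gradient-norm rule for reshaping).
#' @slot finalMarginals model projection means at the final parameters.
#' @slot iterationsUsed iterations actually run.
#' @slot budgetUsed total `sum |a_ij|` at the final parameters.
#' @slot elapsed wall-clock seconds.
#' @export
setClass("FitReport",
  representation(llTrajectory = "numeric", converged = "logical",
                 finalMarginals = "numeric", iterationsUsed = "numeric",
                 budgetUsed = "numeric", elapsed = "numeric")
)

## ---- show methods ----------------------------------------------------------

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster: %d time bins x %d neurons (%g ms bins)\n",
              nrow(object@data), ncol(object@data), object@binWidth))
  cat(sprintf("  mean rate per bin: %.4f\n", mean(object@data)))
})

setMethod("show", "Nonlinearity", function(object) {
  if (object@kind == "sigmoid")
    cat(sprintf("Nonlinearity: sigmoid (beta = %g)\n", object@beta))
  else cat("Nonlinearity: Heaviside step (H(0) = 1)\n")
})

setMethod("show", "ProjectionSet", function(object) {
  cat(sprintf("ProjectionSet: %d projections over %d neurons\n",
              nrow(object@mask), ncol(object@mask)))
  cat(sprintf("  mean in-degree: %.2f | total |weight|: %.3f\n",
              mean(rowSums(object@mask)), sum(abs(object@weights))))
  show(object@nonlinearity)
})

setMethod("show", "RPModel", function(object) {
  cat("RPModel (maximum-entropy over projection means)\n")
  show(object@projections)
  cat(sprintf("  lambda range: [%.3f, %.3f]\n",
              min(object@lambdas), max(object@lambdas)))
})

setMethod("show", "ConstraintSpec", function(object) {
  val <- switch(object@kind, none = "", bounded = sprintf(" (omega = %g)", object@omega),
                sprintf(" (phi = %g)", object@phi))
  cat(sprintf("ConstraintSpec: %s%s\n", object@kind, val))
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: %d iterations, %d/%d projections converged\n",
              as.integer(object@iterationsUsed), sum(object@converged),
              length(object@converged)))
  if (length(object@llTrajectory) && !all(is.na(object@llTrajectory)))
    cat(sprintf("  training LL: %.4f -> %.4f nats/sample\n",
                object@llTrajectory[1],
                object@llTrajectory[length(object@llTrajectory)]))
  cat(sprintf("  synaptic budget used: %.4f\n", object@budgetUsed))
})
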