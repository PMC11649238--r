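#' @include AllClasses.R sampler.R io.R
NULL

#' Construct a ground-truth model with a target firing regime
#'
#' Builds an RP model whose sampled rasters emulate binned cortical
#' population activity. The model has two groups of projections:
#' `nProj` sparse random projections (in-degree `indegree`, weights
#' Normal(1, 1), thresholds 1, multipliers `lambdaScale` times
#' Uniform(0.5, 1.5) draws), which induce the pairwise structure, plus one
#' single-input "bias" projection per neuron (weight 1, threshold 1/2)
#' whose multiplier acts as a per-neuron field. The bias multipliers are
#' tuned by a damped logit-matching loop on probe rasters until every
#' neuron's per-bin firing probability falls inside `targetRateRange` —
#' the same role per-neuron rate terms play in models fitted to real
#' recordings. The default range (0.01, 0.15) reflects the low per-bin
#' firing probabilities of 20 ms-binned cortical data.
#'
#' Per-neuron rate targets are drawn uniformly from the central 60% of the
#' range, so rates are heterogeneous but safely inside it. If the range is
#' not attained within `maxRounds` probe/adjust rounds an error is raised.
#' Fully reproducible from `seed`.
#'
#' @param nNeurons,nProj,indegree population and projection-set geometry
#'   (`nProj` counts only the sparse random projections; the returned model
#'   has `nProj + nNeurons` projections including the bias group).
#' @param nonlinearity a [Nonlinearity-class].
#' @param lambdaScale multiplier scale of the random projections; `0` gives
#'   the uniform model (returned immediately if it meets the range).
#' @param targetRateRange interval in (0, 1) the per-neuron rates must land
#'   in; default `c(0.01, 0.15)`.
#' @param seed integer seed.
#' @param probeSamples probe-raster size per adjustment round.
#' @param maxRounds adjustment cap.
#' @return An [RPModel-class].
#' @export
makeGroundTruthModel <- function(nNeurons, nProj, indegree, nonlinearity,
                                 lambdaScale = 1,
                                 targetRateRange = c(0.01, 0.15),
                                 seed = 1L, probeSamples = 6000,
                                 maxRounds = 40) {
  if (targetRateRange[1] <= 0 || targetRateRange[2] >= 1 ||
      targetRateRange[1] >= targetRateRange[2])
    stop("targetRateRange must be an interval inside (0, 1)")
  lo <- targetRateRange[1]; hi <- targetRateRange[2]
  Prand <- buildSparseProjections(nNeurons, nProj, indegree, nonlinearity,
                                  seed = seed)
  lamRand <- lambdaScale * withSeed(seed + 7L, runif(nProj, 0.5, 1.5))

  ## bias projections: single input, weight 1, threshold 1/2, so each acts
  ## as a per-neuron field h_j * 1{x_j = 1} (up to the sigmoid's slope)
  biasMask <- diag(nNeurons)
  Pfull <- ProjectionSet(rbind(Prand@mask, biasMask),
                         rbind(Prand@weights, biasMask),
                         c(Prand@thresholds, rep(0.5, nNeurons)),
                         nonlinearity)
  assemble <- function(h) RPModel(Pfull, c(lamRand, h))
  probe <- function(M, round) {
    X <- mhSample(M, ChainConfig(nSamples = probeSamples,
                                 burnIn = 200 * nNeurons, thin = nNeurons,
                                 seed = seed + 13L + round))
    colMeans(rasterMatrix(X))
  }

  if (lambdaScale == 0) {
    M <- RPModel(Prand, rep(0, nProj))
    rates <- probe(M, 0L)
    if (all(rates > lo & rates < hi)) return(M)
    stop("uniform model (lambdaScale = 0) does not meet the target rate range")
  }

  ## energy step a unit of bias multiplier adds between x_j = 0 and 1
  gap <- if (nonlinearity@kind == "sigmoid") {
    b <- nonlinearity@beta
    1 / (1 + exp(-b / 2)) - 1 / (1 + exp(b / 2))
  } else 1
  target <- withSeed(seed + 3L, runif(nNeurons, lo + 0.2 * (hi - lo),
                                      hi - 0.2 * (hi - lo)))
  logit <- function(r) log(r / (1 - r))
  h <- rep(0, nNeurons)
  for (round in seq_len(maxRounds)) {
    M <- assemble(h)
    rates <- probe(M, round)
    if (all(rates > lo & rates < hi)) return(M)
    r <- pmin(pmax(rates, 1 / (2 * probeSamples)),
              1 - 1 / (2 * probeSamples))
    h <- h + 0.8 * (logit(r) - logit(target)) / gap
  }
  stop(sprintf(paste("target rate range (%g, %g) not attained after %d",
                     "adjustment rounds (last rates: %.3f-%.3f)"),
               lo, hi, maxRounds, min(rates), max(rates)))
}

#' Sample disjoint train/test rasters from a model
#'
#' Draws `nTrain + nTest` samples from one Metropolis-Hastings chain and
#' splits them into disjoint train and test rasters. The default test size
#' keeps the 4:1 train:test proportion.
#'
#' @param M an [RPModel-class].
#' @param nTrain training samples.
#' @param nTest test samples (default `nTrain / 4`).
#' @param seed integer seed.
#' @param burnIn,thin chain settings (defaults: `200 * n` and `n` flips).
#' @return List with [SpikeRaster-class] elements `train` and `test`.
#' @export
sampleSyntheticRaster <- function(M, nTrain, nTest = round(nTrain / 4),
                                  seed = 1L, burnIn = NA, thin = NA) {
  n <- nNeurons(M)
  if (is.na(burnIn)) burnIn <- 200 * n
  X <- mhSample(M, ChainConfig(nSamples = nTrain + nTest, burnIn = burnIn,
                               thin = thin, seed = seed))
  m <- rasterMatrix(X)
  list(train = SpikeRaster(m[seq_len(nTrain), , drop = FALSE]),
       test = SpikeRaster(m[nTrain + seq_len(nTest), , drop = FALSE]))
}

#' Generate the canonical seeded fixture suite
#'
#' Writes the small reference cases used throughout the test suite to
#' `outDir`:
#' \itemize{
#'   \item `model_n2_closedform.json` — the two-neuron, single-projection
#'     Heaviside model with `lambda = log 3`, whose enumeration fixed point
#'     has projection marginal 1/2 and `Z = 2`.
#'   \item `model_n8.json` / `enum_n8.csv` — an 8-neuron random model and
#'     its exact pattern probabilities (one row per pattern code).
#'   \item `model_n12.json` / `enum_n12.json` — a 12-neuron random model
#'     with its exact `log Z` and neuron/projection marginals.
#'   \item `model_n20_regime.json` / `raster_n20.csv` — a 20-neuron model
#'     in the sparse cortical regime (in-degree 5, thresholds 1,
#'     Normal(1,1) weights) and a sampled raster.
#' }
#' A `manifest.json` records every file with its MD5 checksum; regenerating
#' with the same seed reproduces the checksums bit-identically.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @return The manifest, invisibly (named list of file checksums).
#' @export
makeFixtureSuite <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  pth <- function(f) file.path(outDir, f)

  ## (a) closed-form two-neuron case
  nl <- Nonlinearity("heaviside")
  P2 <- ProjectionSet(matrix(1, 1, 2), matrix(c(1, 1), 1, 2), 1, nl)
  M2 <- RPModel(P2, log(3))
  writeModel(M2, pth("model_n2_closedform.json"),
             metadata = list(seed = seed, provenance = "closed-form fixture"))
  files <- c(files, "model_n2_closedform.json")

  ## (b) enumeration-oracle models
  sig <- Nonlinearity("sigmoid", beta = 2)
  M8 <- RPModel(buildSparseProjections(8, 10, 4, sig, seed = seed + 1L),
                withSeed(seed + 2L, runif(10, 0.3, 1.2)))
  writeModel(M8, pth("model_n8.json"), metadata = list(seed = seed))
  d8 <- enumerateDistribution(M8)
  data.table::fwrite(data.frame(code = 0:(2^8 - 1), prob = d8$probs),
                     pth("enum_n8.csv"))
  M12 <- RPModel(buildSparseProjections(12, 15, 5, sig, seed = seed + 3L),
                 withSeed(seed + 4L, runif(15, 0.3, 1.2)))
  writeModel(M12, pth("model_n12.json"), metadata = list(seed = seed))
  d12 <- enumerateDistribution(M12)
  F12 <- projectionActivations(projections(M12), allPatterns(12))
  jsonlite::write_json(
    list(logZ = d12$logZ,
         neuron_marginals = as.numeric(crossprod(allPatterns(12), d12$probs)),
         projection_marginals = as.numeric(crossprod(F12, d12$probs))),
    pth("enum_n12.json"), digits = NA, auto_unbox = TRUE)
  files <- c(files, "model_n8.json", "enum_n8.csv", "model_n12.json",
             "enum_n12.json")

  ## (c) 20-neuron sparse cortical regime
  M20 <- makeGroundTruthModel(20, 30, 5, sig, lambdaScale = 1,
                              seed = seed + 5L)
  writeModel(M20, pth("model_n20_regime.json"), metadata = list(seed = seed))
  X20 <- mhSample(M20, ChainConfig(nSamples = 2000, burnIn = 4000, thin = 20,
                                   seed = seed + 6L))
  writeRaster(X20, pth("raster_n20.csv"))
  files <- c(files, "model_n20_regime.json", "raster_n20.csv")

  manifest <- list(version = "1.0", seed = seed,
                   checksums = as.list(tools::md5sum(
                     vapply(files, pth, character(1)))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
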