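#' @include AllClasses.R
NULL

.MODEL_FORMAT_VERSION <- "1.0"

#' Read a spike raster from delimited text
#'
#' Rows are time bins, columns are neurons; a header row is optional (it is
#' auto-detected and skipped). Any entry other than 0 or 1 is rejected with
#' its row and column location.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (only sets the expected separator;
#'   detection is automatic otherwise).
#' @param binWidth bin width metadata to attach (default 20 ms).
#' @return A [SpikeRaster-class].
#' @export
readRaster <- function(path, format = c("csv", "tsv"), binWidth = 20) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = "auto",
                          colClasses = "numeric", data.table = FALSE)
  m <- as.matrix(dt)
  bad <- which(!(m == 0 | m == 1) | is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary entry '%s' at row %d, column %d of %s",
                 m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path))
  }
  dimnames(m) <- NULL
  SpikeRaster(m, binWidth = binWidth)
}

#' Write a spike raster to delimited text
#'
#' @param X a [SpikeRaster-class].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(X, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  data.table::fwrite(as.data.frame(rasterMatrix(X)), path, sep = sep,
                     col.names = FALSE)
  invisible(path)
}

#' Random train/test split of a raster
#'
#' Random disjoint row partition; the default held-out fraction 0.2 mirrors
#' the standard 4:1 train:test proportion.
#'
#' @param X a [SpikeRaster-class].
#' @param fractionTest held-out fraction in (0, 1); default 0.2.
#' @param seed integer seed; the partition is reproducible.
#' @return List with [SpikeRaster-class] elements `train` and `test`.
#' @export
splitTrainTest <- function(X, fractionTest = 0.2, seed = 1L) {
  if (fractionTest <= 0 || fractionTest >= 1)
    stop("fractionTest must be in (0, 1)")
  Tn <- nSamples(X)
  nTest <- round(fractionTest * Tn)
  if (nTest < 1 || nTest >= Tn) stop("degenerate split")
  idx <- withSeed(seed, sample.int(Tn))
  testIdx <- idx[seq_len(nTest)]
  m <- rasterMatrix(X)
  list(train = SpikeRaster(m[-testIdx, , drop = FALSE], binWidth(X)),
       test = SpikeRaster(m[testIdx, , drop = FALSE], binWidth(X)))
}

#' Write an RPModel to a structured text file
#'
#' JSON serialization of all model components (mask, weights, thresholds,
#' multipliers, nonlinearity) at full floating-point precision, with a
#' format version tag, so the round-trip is lossless and the file checksum
#' is stable across platforms.
#'
#' @param M an [RPModel-class].
#' @param path output path.
#' @param metadata optional named list stored verbatim (e.g. seed,
#'   provenance).
#' @return `path`, invisibly.
#' @export
writeModel <- function(M, path, metadata = list()) {
  validObject(M)
  P <- M@projections
  obj <- list(
    version = .MODEL_FORMAT_VERSION,
    n_neurons = nNeurons(P),
    n_proj = nProjections(P),
    nonlinearity = list(kind = P@nonlinearity@kind,
                        beta = P@nonlinearity@beta),
    mask = unname(P@mask),
    weights = unname(P@weights),
    thresholds = P@thresholds,
    lambdas = M@lambdas,
    metadata = metadata
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       always_decimal = TRUE, na = "null", pretty = FALSE)
  invisible(path)
}

#' Read an RPModel from a structured text file
#'
#' @param path file written by [writeModel()].
#' @return An [RPModel-class]; the stored metadata is attached as attribute
#'   `"metadata"`.
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != .MODEL_FORMAT_VERSION)
    stop(sprintf("model file version '%s' not supported (expected '%s')",
                 if (is.null(obj$version)) "<missing>" else obj$version,
                 .MODEL_FORMAT_VERSION))
  req <- c("n_neurons", "n_proj", "nonlinearity", "mask", "weights",
           "thresholds", "lambdas")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("model file is missing required field(s): ",
         paste(miss, collapse = ", "))
  nl <- Nonlinearity(obj$nonlinearity$kind,
                     beta = if (is.null(obj$nonlinearity$beta))
                       NA_real_ else obj$nonlinearity$beta)
  toMat <- function(x, nr, nc) {
    m <- matrix(as.numeric(unlist(x)), nrow = nr, ncol = nc, byrow = is.list(x))
    if (is.matrix(x)) m <- x
    storage.mode(m) <- "double"
    m
  }
  mask <- toMat(obj$mask, obj$n_proj, obj$n_neurons)
  weights <- toMat(obj$weights, obj$n_proj, obj$n_neurons)
  P <- ProjectionSet(mask, weights, as.numeric(obj$thresholds), nl)
  M <- RPModel(P, as.numeric(obj$lambdas))
  attr(M, "metadata") <- obj$metadata
  M
}
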