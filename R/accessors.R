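#' @include AllGenerics.R
NULL

#' Accessors for the core classes
#'
#' Read (and where noted, replace) the components of [SpikeRaster-class],
#' [ProjectionSet-class] and [RPModel-class] objects without touching slots
#' directly. Replacement methods revalidate the object.
#'
#' @param x the object.
#' @param value replacement value.
#' @return The requested component; replacement forms return the updated
#'   object.
#' @name accessors
#' @aliases nNeurons nSamples binWidth rasterMatrix nProjections
#'   projectionMask projectionWeights projectionWeights<- thresholds
#'   nonlinearity projections lambdas lambdas<-
NULL

#' @rdname accessors
#' @export
setMethod("nNeurons", "SpikeRaster", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("nSamples", "SpikeRaster", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("binWidth", "SpikeRaster", function(x) x@binWidth)

#' @rdname accessors
#' @export
setMethod("rasterMatrix", "SpikeRaster", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("nNeurons", "ProjectionSet", function(x) ncol(x@mask))

#' @rdname accessors
#' @export
setMethod("nProjections", "ProjectionSet", function(x) nrow(x@mask))

#' @rdname accessors
#' @export
setMethod("projectionMask", "ProjectionSet", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("projectionWeights", "ProjectionSet", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("projectionWeights<-", "ProjectionSet", function(x, value) {
  x@weights <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("thresholds", "ProjectionSet", function(x) x@thresholds)

#' @rdname accessors
#' @export
setMethod("nonlinearity", "ProjectionSet", function(x) x@nonlinearity)

#' @rdname accessors
#' @export
setMethod("projections", "RPModel", function(x) x@projections)

#' @rdname accessors
#' @export
setMethod("lambdas", "RPModel", function(x) x@lambdas)

#' @rdname accessors
#' @export
setMethod("lambdas<-", "RPModel", function(x, value) {
  x@lambdas <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("nNeurons", "RPModel", function(x) nNeurons(x@projections))

#' @rdname accessors
#' @export
setMethod("nProjections", "RPModel", function(x) nProjections(x@projections))
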