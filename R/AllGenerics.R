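#' @include AllClasses.R
NULL

#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @export
setGeneric("rasterMatrix", function(x) standardGeneric("rasterMatrix"))

#' @export
setGeneric("nProjections", function(x) standardGeneric("nProjections"))

#' @export
setGeneric("projectionMask", function(x) standardGeneric("projectionMask"))

#' @export
setGeneric("projectionWeights",
           function(x) standardGeneric("projectionWeights"))

#' @export
setGeneric("projectionWeights<-",
           function(x, value) standardGeneric("projectionWeights<-"))

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
setGeneric("nonlinearity", function(x) standardGeneric("nonlinearity"))

#' @export
setGeneric("projections", function(x) standardGeneric("projections"))

#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))

#' @export
setGeneric("lambdas<-", function(x, value) standardGeneric("lambdas<-"))

#' @export
setGeneric("energy", function(model, x) standardGeneric("energy"))
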