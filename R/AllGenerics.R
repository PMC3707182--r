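#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the S4 classes in seqrep.
#'
#' @param x,object An object.
#' @param ... Further arguments for methods.
#' @name seqrep-generics
#' @keywords internal
NULL

#' @rdname seqrep-generics
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname seqrep-generics
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname seqrep-generics
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @rdname seqrep-generics
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname seqrep-generics
#' @export
setGeneric("runLabels", function(x) standardGeneric("runLabels"))

#' @rdname seqrep-generics
#' @export
setGeneric("betaMatrix", function(x) standardGeneric("betaMatrix"))

#' @rdname seqrep-generics
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname seqrep-generics
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname seqrep-generics
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname seqrep-generics
#' @export
setGeneric("foldPredictions", function(x) standardGeneric("foldPredictions"))

#' @rdname seqrep-generics
#' @export
setGeneric("varianceTable", function(x) standardGeneric("varianceTable"))

#' @rdname seqrep-generics
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname seqrep-generics
#' @export
setGeneric("voxelAreas", function(x) standardGeneric("voxelAreas"))

#' Decompose activation patterns into variance components
#'
#' @param x A [BetaPatterns-class] object.
#' @param ... Further arguments for methods.
#' @export
setGeneric("decomposePatterns",
           function(x, ...) standardGeneric("decomposePatterns"))

#' Ratio of a pattern component's variance to the trial-noise variance
#'
#' @param x A [VarianceComponents-class] object.
#' @param ... Further arguments for methods.
#' @export
setGeneric("specificToNoiseRatio",
           function(x, ...) standardGeneric("specificToNoiseRatio"))
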