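#' Number of points in a patch cloud or graph
#' @param x a PatchCloud or NeighborGraph
#' @return integer count
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PatchCloud", function(x) nrow(x@points))

#' @rdname nPoints
#' @export
setMethod("nPoints", "NeighborGraph", function(x) x@nNodes)

#' Embedding (or aligned-embedding) coordinate matrix
#' @param x a ManifoldEmbedding or ManifoldAlignment
#' @return numeric N x d matrix
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "ManifoldEmbedding", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "ManifoldAlignment", function(x) x@aligned@coords)

#' Retained generalized eigenvalues of an embedding
#' @param x a ManifoldEmbedding
#' @return ascending numeric vector, all > 0
#' @export
setGeneric("spectrum", function(x) standardGeneric("spectrum"))

#' @rdname spectrum
#' @export
setMethod("spectrum", "ManifoldEmbedding", function(x) x@eigenvalues)

#' Estimated or ground-truth transform carried by an object
#' @param x a RegistrationResult or PhantomPair
#' @return a SimilarityTransform2D
#' @export
setGeneric("getTransform", function(x) standardGeneric("getTransform"))

#' @rdname getTransform
#' @export
setMethod("getTransform", "RegistrationResult", function(x) x@transform)

#' @rdname getTransform
#' @export
setMethod("getTransform", "PhantomPair", function(x) x@trueTransform)

#' Transform parameters as a named vector
#' @param x a SimilarityTransform2D
#' @return named numeric (theta, tx, ty, scale)
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))

#' @rdname parameters
#' @export
setMethod("parameters", "SimilarityTransform2D",
  function(x) c(theta = x@theta, tx = x@tx, ty = x@ty, scale = x@scale))
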