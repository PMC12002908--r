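#' @rdname ClonalTree-accessors
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("nMutations", function(x) standardGeneric("nMutations"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("rootClone", function(x) standardGeneric("rootClone"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("mutationIds", function(x) standardGeneric("mutationIds"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("parentMatrix", function(x) standardGeneric("parentMatrix"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("mutationMatrix", function(x) standardGeneric("mutationMatrix"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("cloneFrequencies", function(x) standardGeneric("cloneFrequencies"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("cloneOf", function(x, mutations) standardGeneric("cloneOf"))

#' @rdname ClonalTree-accessors
#' @export
setGeneric("childrenOf", function(x, clone) standardGeneric("childrenOf"))

#' @rdname ancestorMatrix
#' @export
setGeneric("ancestorMatrix", function(x) standardGeneric("ancestorMatrix"))

#' @rdname cloneFractions
#' @export
setGeneric("cloneFractions", function(x, sample = NULL, tol = 1e-6)
  standardGeneric("cloneFractions"))

#' @rdname pairRelationship
#' @export
setGeneric("pairRelationship", function(x, g1, g2)
  standardGeneric("pairRelationship"))

#' @rdname TreeDensity-accessors
#' @export
setGeneric("trees", function(x) standardGeneric("trees"))

#' @rdname TreeDensity-accessors
#' @export
setGeneric("treeWeights", function(x) standardGeneric("treeWeights"))

#' @rdname TreeDensity-accessors
#' @export
setGeneric("treeCounts", function(x) standardGeneric("treeCounts"))

#' @rdname normalizeDensity
#' @export
setGeneric("normalizeDensity", function(x) standardGeneric("normalizeDensity"))

#' @rdname MarkerPanel-accessors
#' @export
setGeneric("markerIndices", function(x) standardGeneric("markerIndices"))

#' @rdname MarkerPanel-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
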