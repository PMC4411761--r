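#' @rdname WeightedStructure-class
#' @param x object
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname RegularTriangulation-class
#' @param x object
#' @export
setGeneric("tetrahedra", function(x) standardGeneric("tetrahedra"))

#' @rdname RegularTriangulation-class
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' @rdname RegularTriangulation-class
#' @export
setGeneric("hullTriangles", function(x) standardGeneric("hullTriangles"))

#' @rdname ChannelNetwork-class
#' @param x object
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname ChannelNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ChannelNetwork-class
#' @export
setGeneric("mouthTriangles", function(x) standardGeneric("mouthTriangles"))

#' @rdname Channel-class
#' @param x object
#' @export
setGeneric("bottleneckRadius", function(x) standardGeneric("bottleneckRadius"))

#' @rdname Channel-class
#' @export
setGeneric("centerline", function(x) standardGeneric("centerline"))

#' @rdname Channel-class
#' @export
setGeneric("channelLength", function(x) standardGeneric("channelLength"))

#' @export
#' @rdname WeightedStructure-class
setMethod("atoms", "WeightedStructure", function(x) x@atoms)

#' @export
#' @rdname RegularTriangulation-class
setMethod("tetrahedra", "RegularTriangulation", function(x) x@tetVerts)

#' @export
#' @rdname RegularTriangulation-class
setMethod("triangles", "RegularTriangulation", function(x) x@triVerts)

#' @export
#' @rdname RegularTriangulation-class
setMethod("hullTriangles", "RegularTriangulation",
          function(x) which(x@triHull))

#' @export
#' @rdname ChannelNetwork-class
setMethod("networkNodes", "ChannelNetwork", function(x) x@nodes)

#' @export
#' @rdname ChannelNetwork-class
setMethod("networkEdges", "ChannelNetwork", function(x) x@edges)

#' @export
#' @rdname ChannelNetwork-class
setMethod("mouthTriangles", "ChannelNetwork", function(x) x@mouthTriangles)

#' @export
#' @rdname Channel-class
setMethod("bottleneckRadius", "Channel", function(x) x@bottleneckRadius)

#' @export
#' @rdname Channel-class
setMethod("centerline", "Channel", function(x) x@centerline)

#' @export
#' @rdname Channel-class
setMethod("channelLength", "Channel", function(x) x@length)

setMethod("show", "WeightedStructure", function(object) {
  cat("WeightedStructure '", object@id, "': ", nrow(object@atoms),
      " atoms (", nrow(object@het), " HETATM kept aside)\n", sep = "")
})

setMethod("show", "RegularTriangulation", function(object) {
  cat("RegularTriangulation: ", nrow(object@tetVerts), " tetrahedra, ",
      nrow(object@triVerts), " triangles (", sum(object@triHull),
      " on hull), ", nrow(object@edgeVerts), " edges, ",
      length(object@vertAlpha), " vertices; ", length(object@hidden),
      " hidden atom(s)\n", sep = "")
})

setMethod("show", "ChannelNetwork", function(object) {
  fin <- object@edges$to != 0L
  cat("ChannelNetwork (alpha = ", object@alpha, "): ",
      nrow(object@nodes), " nodes (", sum(object@nodes$boundary),
      " boundary), ", sum(fin), " interior edges, ",
      length(object@mouthTriangles), " mouth triangles, ",
      length(object@voids), " void component(s) pruned\n", sep = "")
})

setMethod("show", "Channel", function(object) {
  cat("Channel [", object@kind, "]: ", length(object@nodePath),
      " tetrahedra, length ", round(object@length, 2),
      " A, bottleneck radius ", round(object@bottleneckRadius, 3), " A",
      sep = "")
  if (!is.na(object@score))
    cat(", score ", round(object@score, 4), sep = "")
  cat("\n")
})

setMethod("show", "EndpointSet", function(object) {
  cat("EndpointSet: ", length(object@bImp), " boundary representative(s), ",
      length(object@mouthComponents), " mouth(s) at alpha_max = ",
      round(object@alphaMax, 4), " A^2\n", sep = "")
})

setMethod("show", "ChannelProfile", function(object) {
  cat("ChannelProfile '", object@name, "': ", length(object@t),
      " samples on [0, ", round(object@d, 2), "] A\n", sep = "")
})
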