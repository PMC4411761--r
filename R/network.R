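# Channel network: dual graph of the complement of the alpha complex.
# Nodes are complement tetrahedra positioned at their apex (orthocentre
# clamped into the tetrahedron); edges are complement triangles.  A single
# EXTERIOR super-node (id 0) is attached across every mouth triangle.

.EXTERIOR <- 0L

# width floor: complement triangles have positive alpha at alpha = 0, but a
# nonzero working alpha can make widths arbitrarily small
.WIDTH_EPS <- 1e-9

#' Build the channel network of a triangulated structure
#'
#' Restricts to tetrahedra and triangles outside the alpha complex at
#' \code{alpha}, builds their dual graph, annotates mouth triangles
#' (hull triangles in the complement) and boundary nodes, assigns edge
#' costs, optionally prunes inaccessible voids, and computes node depths.
#'
#' Edge width is the local width of the crossing, the clamped aperture of
#' the shared triangle: the largest squared probe radius that fits through
#' the triangular gap (the minimum power distance at the point where the
#' channel actually crosses the triangle), floored at 1e-9 A^2.  Edge
#' length is the length of the centerline polyline the edge contributes:
#' from one tetrahedron orthocentre via the triangle crossing point to the
#' other orthocentre (for exterior edges, orthocentre to crossing point);
#' cost = length / width.
#'
#' @param tri a [RegularTriangulation-class].
#' @param alpha working alpha (A^2), default 0.
#' @param prune drop components not reachable from the exterior
#'   (default TRUE).
#' @return a [ChannelNetwork-class].  An empty network (a solid blob) is
#'   valid and has zero nodes.
#' @export
channelNetwork <- function(tri, alpha = 0, prune = TRUE) {
  compTet <- which(tri@tetSize > alpha)
  compTri <- which(tri@triAlpha > alpha)
  nodes <- data.frame(tet = compTet,
                      x = tri@tetApex[compTet, 1],
                      y = tri@tetApex[compTet, 2],
                      z = tri@tetApex[compTet, 3],
                      width = tri@tetSize[compTet],
                      depth = NA_integer_,
                      boundary = FALSE)
  inComp <- logical(nrow(tri@tetVerts))
  inComp[compTet] <- TRUE

  hull <- tri@triHull[compTri]
  mouths <- compTri[hull]
  interior <- compTri[!hull]

  t1 <- tri@triTets[interior, 1]
  t2 <- tri@triTets[interior, 2]
  stopifnot(all(inComp[t1]), all(inComp[t2]))  # filtration guarantee
  p1 <- tri@tetApex[t1, , drop = FALSE]
  p2 <- tri@tetApex[t2, , drop = FALSE]
  ap <- tri@triApex[interior, , drop = FALSE]
  # floored so coincident apexes (sliver fans) still cost something
  len <- pmax(1e-9, sqrt(rowSums((p1 - ap)^2)) + sqrt(rowSums((ap - p2)^2)))
  wdt <- pmax(.WIDTH_EPS, tri@triAperture[interior])
  edges <- data.frame(tri = interior, from = t1, to = t2,
                      length = len, width = wdt, cost = len / wdt)

  if (length(mouths) > 0) {
    bt <- tri@triTets[mouths, 1]
    stopifnot(all(inComp[bt]))
    blen <- pmax(1e-9, sqrt(rowSums((tri@tetApex[bt, , drop = FALSE] -
                          tri@triApex[mouths, , drop = FALSE])^2)))
    bwdt <- pmax(.WIDTH_EPS, tri@triAperture[mouths])
    edges <- rbind(edges,
                   data.frame(tri = mouths, from = bt, to = .EXTERIOR,
                              length = blen, width = bwdt,
                              cost = blen / bwdt))
    nodes$boundary <- nodes$tet %in% bt
  }
  rownames(edges) <- NULL

  net <- new("ChannelNetwork", triangulation = tri, alpha = alpha,
             nodes = nodes, edges = edges,
             mouthTriangles = as.integer(mouths), voids = list(),
             pruned = FALSE)
  if (prune) net <- pruneVoids(net)
  nodeDepths(net)
}

# igraph over the network; exterior node included as name "0"
.net_graph <- function(net, includeExterior = TRUE) {
  e <- net@edges
  if (!includeExterior) e <- e[e$to != .EXTERIOR, , drop = FALSE]
  verts <- as.character(net@nodes$tet)
  if (includeExterior && nrow(net@edges) > 0 &&
      any(net@edges$to == .EXTERIOR)) verts <- c(verts, "0")
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to),
               weight = e$cost, tri = e$tri, width = e$width,
               len = e$length),
    directed = FALSE, vertices = data.frame(name = verts))
}

#' Prune inaccessible voids from a channel network
#'
#' Keeps only the connected components containing the EXTERIOR node; the
#' removed components are the molecule's voids (buried cavities) and are
#' reported in the \code{voids} slot.  Idempotent.
#'
#' @param net a [ChannelNetwork-class].
#' @return the pruned network.
#' @export
pruneVoids <- function(net) {
  if (nrow(net@nodes) == 0 || !any(net@edges$to == .EXTERIOR)) {
    # nothing reachable: everything is void
    voids <- if (nrow(net@nodes) > 0) list(net@nodes$tet) else list()
    net@voids <- c(net@voids, voids)
    net@nodes <- net@nodes[0, , drop = FALSE]
    net@edges <- net@edges[0, , drop = FALSE]
    net@mouthTriangles <- integer()
    net@pruned <- TRUE
    return(net)
  }
  g <- .net_graph(net)
  comp <- igraph::components(g)
  extComp <- comp$membership[["0"]]
  keepNames <- names(comp$membership)[comp$membership == extComp]
  keep <- as.integer(keepNames[keepNames != "0"])
  lost <- setdiff(net@nodes$tet, keep)
  if (length(lost) > 0) {
    lostM <- comp$membership[as.character(lost)]
    net@voids <- c(net@voids, unname(split(lost, lostM)))
    net@nodes <- net@nodes[net@nodes$tet %in% keep, , drop = FALSE]
    sel <- net@edges$from %in% keep &
      (net@edges$to %in% keep | net@edges$to == .EXTERIOR)
    net@edges <- net@edges[sel, , drop = FALSE]
    net@mouthTriangles <-
      net@edges$tri[net@edges$to == .EXTERIOR]
    rownames(net@nodes) <- rownames(net@edges) <- NULL
  }
  net@pruned <- TRUE
  net
}

#' Assign wave-front depths to network nodes
#'
#' Depth is the minimum hop count to any boundary node (boundary nodes have
#' depth 0), computed as an unweighted breadth-first wave front started at
#' the exterior.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @return the network with depths filled in.
#' @export
nodeDepths <- function(net) {
  if (nrow(net@nodes) == 0) return(net)
  if (!any(net@edges$to == .EXTERIOR)) {
    net@nodes$depth <- NA_integer_
    return(net)
  }
  g <- .net_graph(net)
  d <- igraph::distances(g, v = "0", weights = NA)[1, ]
  d <- d[as.character(net@nodes$tet)]
  d[!is.finite(d)] <- NA  # unreachable (not yet pruned) voids
  net@nodes$depth <- as.integer(d) - 1L
  net
}

# construct a ChannelNetwork directly from tables; used for hand-built and
# random graphs in validation, and by the JSON round trip
#' Assemble a channel network from explicit node/edge tables
#'
#' Low-level constructor for hand-built networks (the normal route is
#' [channelNetwork()]).  Node positions, widths and edge geometry are taken
#' as given; costs are recomputed as length / width unless a \code{cost}
#' column is supplied.
#'
#' @param nodes data.frame with \code{tet}, \code{x}, \code{y}, \code{z},
#'   \code{width}; optional \code{boundary}.
#' @param edges data.frame with \code{tri}, \code{from}, \code{to}
#'   (\code{to = 0} for exterior), \code{length}, \code{width}; optional
#'   \code{cost}.
#' @param triangulation optional backing triangulation.
#' @return a [ChannelNetwork-class].
#' @export
assembleNetwork <- function(nodes, edges, triangulation = NULL) {
  if (is.null(nodes$boundary))
    nodes$boundary <- nodes$tet %in% edges$from[edges$to == .EXTERIOR] |
      nodes$tet %in% edges$to[edges$from == .EXTERIOR]
  nodes$depth <- NA_integer_
  if (is.null(edges$cost)) edges$cost <- edges$length / edges$width
  tr <- if (is.null(triangulation)) .empty_triangulation() else triangulation
  net <- new("ChannelNetwork", triangulation = tr, alpha = 0,
             nodes = nodes, edges = edges,
             mouthTriangles = as.integer(edges$tri[edges$to == .EXTERIOR]),
             voids = list(), pruned = FALSE)
  nodeDepths(net)
}

.empty_triangulation <- function() {
  new("RegularTriangulation",
      structure = weightedStructure(.empty_atoms(), id = "empty"),
      tetVerts = matrix(integer(), 0, 4), tetCenter = matrix(numeric(), 0, 3),
      tetSize = numeric(), tetApex = matrix(numeric(), 0, 3),
      tetAperture = numeric(), tetTris = matrix(integer(), 0, 4),
      triVerts = matrix(integer(), 0, 3), triCenter = matrix(numeric(), 0, 3),
      triSize = numeric(), triAttached = logical(), triAlpha = numeric(),
      triAperture = numeric(), triApex = matrix(numeric(), 0, 3),
      triTets = matrix(integer(), 0, 2), triHull = logical(),
      edgeVerts = matrix(integer(), 0, 2), edgeCenter = matrix(numeric(), 0, 3),
      edgeSize = numeric(), edgeAttached = logical(), edgeAlpha = numeric(),
      vertAlpha = numeric(), vertAttached = logical(),
      hidden = integer(), joggleSeed = NA_integer_)
}

#' Dump a channel network as JSON
#'
#' Nodes with positions, widths and depths; edges with costs.  Intended for
#' debugging and external visualization.
#'
#' @param net a [ChannelNetwork-class].
#' @param path output file.
#' @export
writeNetworkJSON <- function(net, path) {
  jsonlite::write_json(
    list(alpha = net@alpha, nodes = net@nodes, edges = net@edges,
         mouth_triangles = net@mouthTriangles,
         voids = net@voids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
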