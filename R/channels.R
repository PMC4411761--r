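# Significant channels: Dijkstra shortest-cost paths on the channel
# network, iterated edge-disjoint extraction, the widest path tree and
# all-pairs important pores.  All channel searches run on the finite
# subgraph: the EXTERIOR super-node is never an allowed through-node.

# build a Channel object from an ordered tet-id path
.make_channel <- function(net, tetPath, kind = "pore") {
  tri <- net@triangulation
  n <- length(tetPath)
  e <- net@edges
  ekey <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  triPath <- integer(0)
  eidx <- integer(0)
  if (n > 1) {
    want <- paste(pmin(tetPath[-n], tetPath[-1]),
                  pmax(tetPath[-n], tetPath[-1]))
    eidx <- match(want, ekey)
    if (anyNA(eidx)) stop("path tetrahedra are not adjacent in the network")
    triPath <- e$tri[eidx]
  }
  pts <- matrix(NA_real_, 2L * n - 1L, 3)
  radii <- numeric(2L * n - 1L)
  bare <- nrow(tri@tetVerts) == 0  # hand-assembled network without geometry
  if (bare) {
    ni <- match(tetPath, net@nodes$tet)
    pts[seq(1, 2 * n - 1, by = 2), ] <-
      as.matrix(net@nodes[ni, c("x", "y", "z")])
    radii[seq(1, 2 * n - 1, by = 2)] <-
      sqrt(pmax(1e-9, net@nodes$width[ni]))
    if (n > 1) {
      mid <- (pts[seq(1, 2 * n - 3, by = 2), , drop = FALSE] +
                pts[seq(3, 2 * n - 1, by = 2), , drop = FALSE]) / 2
      pts[seq(2, 2 * n - 2, by = 2), ] <- mid
      radii[seq(2, 2 * n - 2, by = 2)] <- sqrt(pmax(1e-9, e$width[eidx]))
    }
  } else {
    pts[seq(1, 2 * n - 1, by = 2), ] <- tri@tetApex[tetPath, , drop = FALSE]
    radii[seq(1, 2 * n - 1, by = 2)] <-
      sqrt(pmax(1e-9, tri@tetAperture[tetPath]))
    if (n > 1) {
      # the channel crosses each triangle at its most-open point; the
      # radius there is the orthosphere radius of the flanking atoms
      # (clamped to the gap for sliver triangles)
      pts[seq(2, 2 * n - 2, by = 2), ] <- tri@triApex[triPath, , drop = FALSE]
      radii[seq(2, 2 * n - 2, by = 2)] <-
        sqrt(pmax(1e-9, tri@triAperture[triPath]))
    }
  }
  seg <- if (n > 1) sqrt(rowSums(diff(pts)^2)) else numeric(0)
  arc <- c(0, cumsum(seg))
  bn <- min(radii)
  tetAtoms <- if (bare) matrix(NA_integer_, n, 4) else
    tri@tetVerts[tetPath, , drop = FALSE]
  triAtoms <- if (bare) matrix(NA_integer_, max(0L, n - 1L), 3) else
    tri@triVerts[triPath, , drop = FALSE]
  new("Channel", nodePath = as.integer(tetPath),
      triPath = as.integer(triPath), centerline = pts, arc = arc,
      radii = radii, tetAtoms = tetAtoms, triAtoms = triAtoms,
      length = arc[length(arc)], bottleneckRadius = bn,
      straightness = NA_real_, score = NA_real_, kind = kind,
      structure = tri@structure@atoms)
}

#' Shortest-cost channel between two network nodes
#'
#' Dijkstra on the channel network under the cost = length / width edge
#' weights; the exterior node is excluded so pores cannot shortcut through
#' open space.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param src,dst tetrahedron ids of the endpoints.
#' @param kind channel kind label.
#' @return a [Channel-class], or \code{NULL} when the endpoints are
#'   disconnected.
#' @export
shortestChannel <- function(net, src, dst, kind = "pore") {
  if (src == dst)
    stop("degenerate channel: source and destination coincide",
         call. = FALSE)
  if (!all(c(src, dst) %in% net@nodes$tet))
    stop("endpoints must be nodes of the pruned network", call. = FALSE)
  g <- .net_graph(net, includeExterior = FALSE)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = as.character(src),
                           to = as.character(dst), weights = NULL,
                           output = "vpath"))
  v <- sp$vpath[[1]]
  if (length(v) == 0) return(NULL)
  .make_channel(net, as.integer(names(v)), kind = kind)
}

#' Iterated edge-disjoint channels
#'
#' Repeats the shortest-cost search; after each iteration the used edges'
#' costs are raised to the saturation constant 1 + sum of all original
#' costs, which any path of unsaturated edges beats.  A further channel
#' that would reuse a saturated edge is discarded and the iteration stops,
#' so the returned channels are pairwise edge-disjoint.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param src,dst endpoints (tetrahedron ids).
#' @param count maximum number of channels (>= 1).
#' @param kind channel kind label.
#' @return list of [Channel-class] (possibly shorter than \code{count}).
#' @export
disjointChannels <- function(net, src, dst, count = 3L, kind = "pore") {
  if (count < 1) stop("count must be >= 1", call. = FALSE)
  fin <- net@edges$to != .EXTERIOR
  saturation <- 1 + sum(net@edges$cost[fin])
  work <- net
  out <- list()
  saturated <- integer(0)
  for (i in seq_len(count)) {
    ch <- shortestChannel(work, src, dst, kind = kind)
    if (is.null(ch)) break
    if (any(ch@triPath %in% saturated)) break
    out[[length(out) + 1L]] <- ch
    hit <- work@edges$tri %in% ch@triPath
    work@edges$cost[hit] <- saturation
    saturated <- c(saturated, ch@triPath)
  }
  out
}

#' Widest path tree of the channel network
#'
#' Maximum spanning tree (forest) under edge width.  For any node pair the
#' tree path maximises, over all network paths, the minimum edge width.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @return a [WidestPathTree-class].
#' @export
widestPathTree <- function(net) {
  e <- net@edges[net@edges$to != .EXTERIOR, , drop = FALSE]
  if (nrow(e) == 0)
    return(new("WidestPathTree", edges = e, nodes = net@nodes$tet,
               network = net))
  g <- .net_graph(net, includeExterior = FALSE)
  mst <- igraph::mst(g, weights = -igraph::E(g)$width)
  keep <- igraph::E(mst)$tri
  new("WidestPathTree", edges = e[e$tri %in% keep, , drop = FALSE],
      nodes = net@nodes$tet, network = net)
}

#' Prune a widest path tree to the paths between important nodes
#'
#' Repeatedly deletes degree-1 nodes that are not important until none
#' remain; the result is the union of the pairwise tree paths between the
#' important nodes.
#'
#' @param tree a [WidestPathTree-class].
#' @param important tetrahedron ids to retain.
#' @return the pruned tree.
#' @export
pruneTree <- function(tree, important) {
  e <- tree@edges
  nodes <- tree@nodes
  repeat {
    deg <- table(factor(c(e$from, e$to), levels = nodes))
    drop <- nodes[deg <= 1 & !(nodes %in% important)]
    if (length(drop) == 0) break
    nodes <- setdiff(nodes, drop)
    e <- e[!(e$from %in% drop) & !(e$to %in% drop), , drop = FALSE]
  }
  new("WidestPathTree", edges = e, nodes = as.integer(nodes),
      network = tree@network)
}

#' All-pairs important pores
#'
#' A shortest-cost channel for each unordered pair among the top-k
#' persistence-ranked boundary representatives; channels with identical
#' triangle paths are collapsed.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param endpoints an [EndpointSet-class].
#' @param k number of boundary nodes used (defaults to all of bImp).
#' @return list of [Channel-class], sorted by increasing path cost.
#' @export
importantPores <- function(net, endpoints, k = length(endpoints@bImp)) {
  b <- utils::head(endpoints@bImp, k)
  if (length(b) < 2) return(list())
  out <- list()
  seen <- character(0)
  for (i in seq_len(length(b) - 1)) {
    for (j in seq(i + 1, length(b))) {
      ch <- tryCatch(shortestChannel(net, b[i], b[j], kind = "pore"),
                     error = function(e) NULL)
      if (is.null(ch)) next
      key <- paste(sort(ch@triPath), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- ch
    }
  }
  if (length(out) > 1) {
    cost <- vapply(out, function(ch) .channel_cost(net, ch), numeric(1))
    out <- out[order(cost)]
  }
  out
}

.channel_cost <- function(net, ch) {
  sum(net@edges$cost[match(ch@triPath, net@edges$tri)])
}

#' Best channel(s) from an active site to the exterior
#'
#' Runs the deepest-node selection for the site, then iterated
#' edge-disjoint searches to every boundary representative, returning the
#' lowest-cost channels.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param site matrix of site atom coordinates (see [siteAtoms()]).
#' @param endpoints an [EndpointSet-class].
#' @param count channels retained per endpoint pair (default 3).
#' @return list of [Channel-class] sorted by cost.
#' @export
activeSiteChannels <- function(net, site, endpoints, count = 3L) {
  start <- activeSiteNode(net, site)
  out <- list()
  for (b in endpoints@bImp) {
    if (b == start) next
    chs <- disjointChannels(net, start, b, count = count,
                            kind = "active-site")
    out <- c(out, chs)
  }
  if (length(out) > 1) {
    cost <- vapply(out, function(ch) .channel_cost(net, ch), numeric(1))
    out <- out[order(cost)]
  }
  out
}

#' Serialize a channel as JSON
#'
#' Node and triangle ids, centerline coordinates, per-sample radii, and the
#' atoms lining each tetrahedron.
#'
#' @param ch a [Channel-class].
#' @param path output file.
#' @export
writeChannelJSON <- function(ch, path) {
  jsonlite::write_json(
    list(kind = ch@kind, nodes = ch@nodePath, triangles = ch@triPath,
         centerline = ch@centerline, arc = ch@arc, radii = ch@radii,
         length = ch@length, bottleneck_radius = ch@bottleneckRadius,
         straightness = ch@straightness, score = ch@score,
         lining_atoms = ch@tetAtoms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
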