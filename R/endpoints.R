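# Endpoint selection: mouth detection by alpha scan, persistence-ranked
# boundary representatives, and the deepest-node rule for active sites.
#
# "Persistence" of an opening is operationalised as the squared orthoradius
# (size value) of its widest triangle: the aperture exists in the
# complement for the alpha interval [0, size), so the size is the lifetime
# of the opening measured from 0.  The attachment-inherited entry alpha is
# deliberately NOT used for ranking: on any rough convex surface the
# convex hull skips over inward-jittered atoms, producing near-degenerate
# "sliver" tetrahedra whose empty orthospheres are orders of magnitude
# larger than any physical aperture; their faces inherit those alphas and
# would dominate every entry-time ranking while representing no opening at
# all.  The own orthoradius of a triangle is bounded by the geometry of
# the gap it spans and is therefore a robust proxy for the persistence
# pairing.  This approximates full persistence pairing.

#' Scan alpha for the mouth-count maximum
#'
#' A hull triangle is an open mouth at growth \eqn{\alpha} when it is
#' still in the complement (entry alpha > \eqn{\alpha}) and its aperture
#' is still open (own squared orthoradius > \eqn{\alpha}).  Candidate
#' alphas are 0 and the distinct thresholds at which a hull triangle
#' closes, in [0, Inf).  For each candidate, mouths are the connected
#' components (via shared hull edges) of open hull triangles.  Returns the
#' smallest alpha maximising the mouth count, and the components at that
#' alpha.
#'
#' @param tri a [RegularTriangulation-class].
#' @return list with \code{alphaMax} (A^2), \code{mouthComponents} (list of
#'   hull-triangle id vectors) and \code{counts} (data.frame of the scan).
#' @export
mouthScan <- function(tri) {
  hullIds <- which(tri@triHull)
  thr <- pmin(tri@triAlpha[hullIds], tri@triAperture[hullIds])
  cand <- sort(unique(c(0, thr[thr >= 0])))
  counts <- integer(length(cand))
  comps <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    comps[[i]] <- .mouth_components(tri, hullIds[thr > cand[i]])
    counts[i] <- length(comps[[i]])
  }
  best <- which.max(counts)  # ties broken toward the smallest alpha
  list(alphaMax = cand[best], mouthComponents = comps[[best]],
       counts = data.frame(alpha = cand, mouths = counts))
}

# connected components of a set of hull triangles under shared-edge
# adjacency
.mouth_components <- function(tri, ids) {
  if (length(ids) == 0) return(list())
  n <- nrow(tri@structure@atoms)
  v <- tri@triVerts[ids, , drop = FALSE]
  ek <- c(.row_key(v[, c(1, 2), drop = FALSE], n),
          .row_key(v[, c(1, 3), drop = FALSE], n),
          .row_key(v[, c(2, 3), drop = FALSE], n))
  owner <- rep(seq_along(ids), 3)
  pairs <- split(owner, ek)
  pairs <- pairs[lengths(pairs) == 2]
  if (length(pairs) > 0) {
    em <- do.call(rbind, pairs)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  }
  m <- igraph::components(g)$membership[seq_along(ids)]
  unname(lapply(split(seq_along(ids), m), function(i) ids[i]))
}

# Widest-path access value for every node: the largest W such that a
# probe of squared radius W can travel from the node to the deep interior
# (nodes with depth >= half the maximum depth).  Computed by max-min
# relaxation over the edges, which converges on any graph.  A mouth is
# only as significant as the widest probe it admits to the interior;
# hull-sliver openings lead nowhere wide and rank at the bottom.
.access_width <- function(net) {
  nodes <- net@nodes
  if (nrow(nodes) == 0) return(numeric(0))
  e <- net@edges[net@edges$to != .EXTERIOR, , drop = FALSE]
  maxDepth <- suppressWarnings(max(nodes$depth, na.rm = TRUE))
  if (!is.finite(maxDepth)) maxDepth <- 0L
  D <- max(1L, maxDepth %/% 2L)
  deep <- nodes$depth >= D
  W <- stats::setNames(rep(-Inf, nrow(nodes)), nodes$tet)
  if (!any(deep) || nrow(e) == 0) {
    # shallow molecule: best incident gap stands in for interior access
    for (i in seq_len(nrow(net@edges))) {
      ed <- net@edges[i, ]
      for (tet in c(ed$from, ed$to)) {
        key <- as.character(tet)
        if (tet != .EXTERIOR && key %in% names(W))
          W[key] <- max(W[key], ed$width)
      }
    }
    return(W)
  }
  W[deep] <- Inf
  fi <- match(e$from, nodes$tet)
  ti <- match(e$to, nodes$tet)
  repeat {
    cand1 <- pmin(W[fi], e$width)
    cand2 <- pmin(W[ti], e$width)
    newW <- W
    upd <- tapply(c(cand1, cand2), c(ti, fi), max)
    pos <- as.integer(names(upd))
    newW[pos] <- pmax(newW[pos], unname(upd))
    if (all(newW <= W + 1e-12)) break
    W <- newW
  }
  W
}

#' Persistence-ranked boundary representatives
#'
#' One representative node per mouth: the complement tetrahedron incident
#' to the mouth triangle with the widest interior access, where the access
#' value of a triangle is the minimum of its own aperture (squared
#' orthoradius) and the widest-path width from its tetrahedron to the deep
#' interior.  Mouths whose access value falls below \code{minFraction}
#' times the best mouth's value are discarded as surface noise (hull
#' slivers open onto the exterior film but admit no probe into the
#' molecule).  The list is sorted by decreasing access value and truncated
#' to \code{k}.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param mouthComponents as returned by [mouthScan()].
#' @param k number of boundary nodes retained (default 10); must be at
#'   least 2 for pore extraction.
#' @param alphaMax the alpha at which the mouths were extracted (stored in
#'   the result).
#' @param minFraction relative noise gate on the access value.
#' @return an [EndpointSet-class].
#' @export
rankBoundaryNodes <- function(net, mouthComponents, k = 10L,
                              alphaMax = 0, minFraction = 0.1) {
  if (k < 2) stop("pore extraction needs k >= 2", call. = FALSE)
  tri <- net@triangulation
  W <- .access_width(net)
  reps <- integer(0)
  pers <- numeric(0)
  for (comp in mouthComponents) {
    tets <- tri@triTets[comp, 1]
    ok <- tets %in% net@nodes$tet
    if (!any(ok)) next
    val <- pmin(tri@triAperture[comp[ok]],
                W[as.character(tets[ok])])
    best <- which.max(val)
    tet <- tets[ok][best]
    if (!(tet %in% reps)) {
      reps <- c(reps, tet)
      pers <- c(pers, val[best])
    }
  }
  if (length(reps) > 0) {
    keepNoise <- pers >= minFraction * max(pers)
    reps <- reps[keepNoise]
    pers <- pers[keepNoise]
  }
  o <- order(-pers, reps)
  reps <- reps[o]
  pers <- pers[o]
  keep <- seq_len(min(k, length(reps)))
  new("EndpointSet", activeSiteNode = NA_integer_,
      bImp = as.integer(reps[keep]), alphaMax = alphaMax,
      mouthComponents = mouthComponents,
      persistence = stats::setNames(pers[keep], reps[keep]))
}

#' Full endpoint selection for pore extraction
#'
#' Convenience wrapper: [mouthScan()] then [rankBoundaryNodes()].
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param k boundary nodes retained.
#' @return an [EndpointSet-class].
#' @export
selectEndpoints <- function(net, k = 10L) {
  ms <- mouthScan(net@triangulation)
  rankBoundaryNodes(net, ms$mouthComponents, k = k,
                    alphaMax = ms$alphaMax)
}

#' Representative network node for an active site
#'
#' For each site atom, the nearest node by Euclidean distance gives the
#' candidate set N(A); the member of N(A) with maximum depth is returned.
#' (The centroid rule fails for large ligands whose centroid sits far from
#' the deepest interacting node.)  Ties are broken by larger node width,
#' then lower tetrahedron id.
#'
#' @param net a pruned [ChannelNetwork-class] with depths.
#' @param siteAtoms matrix (n x 3) of site atom coordinates.
#' @return tetrahedron id of the representative node.
#' @export
activeSiteNode <- function(net, siteAtoms) {
  if (nrow(net@nodes) == 0)
    stop("no channel network: structure has no accessible empty space",
         call. = FALSE)
  siteAtoms <- matrix(as.numeric(siteAtoms), ncol = 3)
  if (nrow(siteAtoms) < 1) stop("need at least one site atom", call. = FALSE)
  pos <- as.matrix(net@nodes[, c("x", "y", "z")])
  nearest <- vapply(seq_len(nrow(siteAtoms)), function(i) {
    d2 <- (pos[, 1] - siteAtoms[i, 1])^2 + (pos[, 2] - siteAtoms[i, 2])^2 +
      (pos[, 3] - siteAtoms[i, 3])^2
    which.min(d2)
  }, integer(1))
  cand <- unique(nearest)
  o <- order(-net@nodes$depth[cand], -net@nodes$width[cand],
             net@nodes$tet[cand])
  net@nodes$tet[cand[o[1]]]
}

#' Coordinates of a user-specified site
#'
#' Site atoms come either from a residue list ("A:123" strings against the
#' ball-model atoms) or from all atoms of a named HETATM ligand.
#'
#' @param s a [WeightedStructure-class].
#' @param residues character vector like \code{c("A:123", "A:145")}.
#' @param ligand 3-letter HETATM residue code.
#' @return matrix (n x 3) of coordinates.
#' @export
siteAtoms <- function(s, residues = NULL, ligand = NULL) {
  if (!is.null(residues)) {
    parts <- strsplit(residues, ":", fixed = TRUE)
    ch <- vapply(parts, `[`, "", 1L)
    rn <- as.integer(vapply(parts, `[`, "", 2L))
    sel <- paste0(s@atoms$chain, ":", s@atoms$resno) %in% paste0(ch, ":", rn)
    m <- as.matrix(s@atoms[sel, c("x", "y", "z")])
  } else if (!is.null(ligand)) {
    sel <- s@het$resname == toupper(ligand)
    m <- as.matrix(s@het[sel, c("x", "y", "z")])
  } else stop("specify residues or ligand", call. = FALSE)
  if (nrow(m) == 0) stop("no atoms match the site specification",
                         call. = FALSE)
  dimnames(m) <- NULL
  m
}
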