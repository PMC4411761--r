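# Regular triangulation, orthospheres and the alpha-complex filtration.
#
# The combinatorics come from the C++ incremental builder (rt_build_cpp),
# which works on deterministically joggled coordinates; all geometry
# (orthocentres, size values, alpha values) is then computed on the
# original, unjoggled coordinates.

#' Power distance from a weighted point
#'
#' \eqn{\pi_p(x) = \|x - p\|^2 - w}, zero exactly on the ball surface.
#'
#' @param center 3-vector, the atom centre.
#' @param weight squared ball radius (A^2).
#' @param x query point (3-vector) or matrix with one point per row.
#' @return numeric vector of power distances (A^2).
#' @export
powerDistance <- function(center, weight, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2 +
    (x[, 3] - center[3])^2 - weight
}

#' Orthosphere of 2--4 weighted points
#'
#' The sphere with zero power to every defining weighted point; for fewer
#' than 4 points the centre is constrained to the affine hull of the
#' centres.  The returned \code{size} is the squared orthoradius, which may
#' be negative.
#'
#' @param centers k x 3 matrix (k in 2..4).
#' @param weights squared radii, length k.
#' @return list with \code{center} (3-vector) and \code{size} (A^2).
#' @export
orthosphere <- function(centers, weights) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 2 || k > 4) stop("orthosphere needs 2 to 4 points", call. = FALSE)
  res <- orthospheres_cpp(centers, as.numeric(weights),
                          matrix(seq_len(k), nrow = 1))
  if (!res$ok[1])
    stop("degenerate input: affinely dependent centers", call. = FALSE)
  list(center = as.numeric(res$center[1, ]), size = res$size[1])
}

# fast group minimum: min of x within groups g (integers 1..ng)
.grp_min <- function(x, g, ng) {
  o <- order(g, x)
  gg <- g[o]
  out <- rep(NA_real_, ng)
  first <- !duplicated(gg)
  out[gg[first]] <- x[o][first]
  out
}

.grp_any <- function(flag, g, ng) {
  out <- logical(ng)
  if (any(flag)) out[unique(g[flag])] <- TRUE
  out
}

# rowwise sort of 2- or 3-column integer matrices, vectorized
.sort_rows <- function(m) {
  out <- if (ncol(m) == 2) {
    cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  } else {
    lo <- pmin(m[, 1], m[, 2], m[, 3])
    hi <- pmax(m[, 1], m[, 2], m[, 3])
    cbind(lo, m[, 1] + m[, 2] + m[, 3] - lo - hi, hi)
  }
  dimnames(out) <- NULL
  out
}

# sorted-row key for vertex tuples (exact in doubles for n < ~1e5)
.row_key <- function(m, n) {
  K <- as.numeric(n + 1)
  s <- .sort_rows(m)
  if (ncol(m) == 3) (s[, 1] * K + s[, 2]) * K + s[, 3]
  else s[, 1] * K + s[, 2]
}

#' Regular (weighted Delaunay) triangulation with alpha filtration
#'
#' Computes the regular triangulation of the atom balls by incremental
#' insertion on the lifted points (equivalent to the lower convex hull of
#' \eqn{(x, \|x\|^2 - w)}), then fills in per-simplex orthocentres, size
#' values, attachment flags and alpha values for tetrahedra, triangles,
#' edges and vertices.  Numerically degenerate (cospherical/coplanar)
#' configurations are resolved by a deterministic joggle of magnitude
#' \code{joggle}; if the builder reports precision loss the joggle is
#' re-drawn from the next seed.
#'
#' A simplex of dimension < 3 is \emph{attached} when its orthocentre has
#' power less than the simplex size to some vertex of a coface (the weighted
#' Gabriel test); its alpha value is then inherited as the minimum alpha
#' value of its cofaces, otherwise it equals its own size value.
#'
#' @param s a [WeightedStructure-class] (at least 4 atoms with affinely
#'   independent centres).
#' @param joggle perturbation magnitude (A).
#' @param seed joggle seed.
#' @param maxAttempts number of joggle re-draws before giving up.
#' @return a [RegularTriangulation-class].
#' @export
regularTriangulation <- function(s, joggle = 1e-8, seed = 1L,
                                 maxAttempts = 5L) {
  a <- s@atoms
  n <- nrow(a)
  if (n < 4) stop("need at least 4 atoms", call. = FALSE)
  coords <- as.matrix(a[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  w <- a$weight

  res <- NULL
  usedSeed <- NA_integer_
  for (k in seq_len(maxAttempts)) {
    sk <- as.integer(seed) + k - 1L
    jog <- .with_seed(sk, matrix(stats::runif(3 * n, -joggle, joggle),
                                 ncol = 3))
    r <- rt_build_cpp(coords + jog, w)
    if (r$status == "ok") { res <- r; usedSeed <- sk; break }
    if (r$status == "degenerate")
      stop("degenerate input: ", r$why, call. = FALSE)
  }
  if (is.null(res))
    stop("triangulation failed after ", maxAttempts,
         " joggle attempts (precision loss)", call. = FALSE)

  tets <- res$tets
  m <- nrow(tets)
  if (m == 0) stop("degenerate input: empty triangulation", call. = FALSE)

  ## triangles: the 4 facets of every tet, de-duplicated
  facets <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                  tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  oppVert <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  facetTet <- rep(seq_len(m), 4)
  fkey <- .row_key(facets, n)
  ukey <- sort(unique(fkey))
  triId <- match(fkey, ukey)
  nt <- length(ukey)
  first <- !duplicated(triId)
  triVerts <- .sort_rows(facets[first, , drop = FALSE])
  triVerts <- triVerts[order(triId[first]), , drop = FALSE]

  triTets <- matrix(NA_integer_, nt, 2)
  triOpp <- matrix(NA_integer_, nt, 2)
  o <- order(triId)
  tid <- triId[o]
  pos <- ifelse(duplicated(tid), 2L, 1L)
  triTets[cbind(tid, pos)] <- facetTet[o]
  triOpp[cbind(tid, pos)] <- oppVert[o]

  tetTris <- matrix(triId, m, 4)

  ## hull triangles as reported by the builder
  hull <- res$hull
  hkey <- .row_key(hull[, 1:3, drop = FALSE], n)
  triHull <- logical(nt)
  triHull[match(hkey, ukey)] <- TRUE
  inc <- rowSums(!is.na(triTets))
  if (any(inc[triHull] != 1L) || any(inc[!triHull] != 2L))
    stop("internal error: hull/interior incidence mismatch")

  ## edges: the 3 sides of every triangle
  sides <- rbind(triVerts[, c(1, 2)], triVerts[, c(1, 3)],
                 triVerts[, c(2, 3)])
  eOpp <- c(triVerts[, 3], triVerts[, 2], triVerts[, 1])
  eTri <- rep(seq_len(nt), 3)
  ekey <- .row_key(sides, n)
  uek <- sort(unique(ekey))
  edgeId <- match(ekey, uek)
  ne <- length(uek)
  efirst <- !duplicated(edgeId)
  edgeVerts <- sides[efirst, , drop = FALSE]
  edgeVerts <- edgeVerts[order(edgeId[efirst]), , drop = FALSE]

  ## orthocentres and sizes
  ot <- orthospheres_cpp(coords, w, tets)
  otr <- orthospheres_cpp(coords, w, triVerts)
  oe <- orthospheres_cpp(coords, w, edgeVerts)
  if (any(!ot$ok) || any(!otr$ok) || any(!oe$ok))
    stop("degenerate simplex encountered in orthosphere computation",
         call. = FALSE)

  pw <- function(q, x) {
    (x[, 1] - coords[q, 1])^2 + (x[, 2] - coords[q, 2])^2 +
      (x[, 3] - coords[q, 3])^2 - w[q]
  }

  ## triangle attachment & alpha: Gabriel test against the opposite vertex
  ## of each incident tet, then inherit min coface alpha when attached
  tlist <- data.frame(tri = rep(seq_len(nt), 2),
                      tet = as.vector(triTets), opp = as.vector(triOpp))
  tlist <- tlist[!is.na(tlist$tet), ]
  att <- pw(tlist$opp, otr$center[tlist$tri, , drop = FALSE]) <
    otr$size[tlist$tri]
  triAttached <- .grp_any(att, tlist$tri, nt)
  cofMin <- .grp_min(ot$size[tlist$tet], tlist$tri, nt)
  triAlpha <- ifelse(triAttached, cofMin, otr$size)

  ## edges
  elist <- data.frame(edge = edgeId, tri = eTri, opp = eOpp)
  atte <- pw(elist$opp, oe$center[elist$edge, , drop = FALSE]) <
    oe$size[elist$edge]
  edgeAttached <- .grp_any(atte, elist$edge, ne)
  ecofMin <- .grp_min(triAlpha[elist$tri], elist$edge, ne)
  edgeAlpha <- ifelse(edgeAttached, ecofMin, oe$size)

  ## clamped apertures: the largest probe that fits through each gap.
  ## Raw size values are monotone under the face relation, so sliver
  ## simplices inherit arbitrarily large orthoradii that do not
  ## correspond to any physical opening; clamping to the simplex itself
  ## restores the probe interpretation.
  edgeP1 <- coords[edgeVerts[, 1], , drop = FALSE]
  edgeP2 <- coords[edgeVerts[, 2], , drop = FALSE]
  ed <- edgeP2 - edgeP1
  eu <- rowSums((oe$center - edgeP1) * ed) / pmax(rowSums(ed^2), 1e-300)
  edgeInside <- eu >= 0 & eu <= 1
  edgeAperture <- ifelse(edgeInside, oe$size,
                         pmax(-w[edgeVerts[, 1]], -w[edgeVerts[, 2]]))
  edgeApex <- oe$center
  clampLo <- !edgeInside & -w[edgeVerts[, 1]] >= -w[edgeVerts[, 2]]
  clampHi <- !edgeInside & !clampLo
  edgeApex[clampLo, ] <- edgeP1[clampLo, , drop = FALSE]
  edgeApex[clampHi, ] <- edgeP2[clampHi, , drop = FALSE]

  triEdges <- matrix(edgeId, nt, 3)
  pa <- coords[triVerts[, 1], , drop = FALSE]
  pb <- coords[triVerts[, 2], , drop = FALSE]
  pc <- coords[triVerts[, 3], , drop = FALSE]
  v0 <- pb - pa; v1 <- pc - pa; v2 <- otr$center - pa
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- pmax(d00 * d11 - d01 * d01, 1e-300)
  bb <- (d11 * d20 - d01 * d21) / den
  gg <- (d00 * d21 - d01 * d20) / den
  triInside <- bb >= -1e-12 & gg >= -1e-12 & (1 - bb - gg) >= -1e-12
  eap <- matrix(edgeAperture[triEdges], nt, 3)
  bestEdge <- max.col(eap, ties.method = "first")
  bestId <- triEdges[cbind(seq_len(nt), bestEdge)]
  triApex <- otr$center
  triApex[!triInside, ] <- edgeApex[bestId[!triInside], , drop = FALSE]
  # aperture = min power distance over ALL atoms at the crossing point:
  # the squared radius of the largest probe centred there, accounting for
  # atoms beyond the three that span the triangle
  triAperture <- min_power_cpp(coords, w, triApex)

  ## tetrahedron apexes: orthocentre clamped into the tetrahedron; sliver
  ## tetrahedra get the apex of their widest facet
  ta <- coords[tets[, 1], , drop = FALSE]
  m1 <- coords[tets[, 2], , drop = FALSE] - ta
  m2 <- coords[tets[, 3], , drop = FALSE] - ta
  m3 <- coords[tets[, 4], , drop = FALSE] - ta
  rhs <- ot$center - ta
  det3 <- m1[, 1] * (m2[, 2] * m3[, 3] - m2[, 3] * m3[, 2]) -
    m1[, 2] * (m2[, 1] * m3[, 3] - m2[, 3] * m3[, 1]) +
    m1[, 3] * (m2[, 1] * m3[, 2] - m2[, 2] * m3[, 1])
  cross23 <- cbind(m2[, 2] * m3[, 3] - m2[, 3] * m3[, 2],
                   m2[, 3] * m3[, 1] - m2[, 1] * m3[, 3],
                   m2[, 1] * m3[, 2] - m2[, 2] * m3[, 1])
  cross31 <- cbind(m3[, 2] * m1[, 3] - m3[, 3] * m1[, 2],
                   m3[, 3] * m1[, 1] - m3[, 1] * m1[, 3],
                   m3[, 1] * m1[, 2] - m3[, 2] * m1[, 1])
  cross12 <- cbind(m1[, 2] * m2[, 3] - m1[, 3] * m2[, 2],
                   m1[, 3] * m2[, 1] - m1[, 1] * m2[, 3],
                   m1[, 1] * m2[, 2] - m1[, 2] * m2[, 1])
  dd <- ifelse(det3 == 0, 1e-300, det3)
  b1 <- rowSums(rhs * cross23) / dd
  b2 <- rowSums(rhs * cross31) / dd
  b3 <- rowSums(rhs * cross12) / dd
  tetInside <- det3 != 0 & b1 >= -1e-12 & b2 >= -1e-12 & b3 >= -1e-12 &
    (b1 + b2 + b3) <= 1 + 1e-12
  faceAp <- matrix(triAperture[tetTris], m, 4)
  bestFace <- tetTris[cbind(seq_len(m), max.col(faceAp, ties.method = "first"))]
  tetApex <- ot$center
  tetApex[!tetInside, ] <- triApex[bestFace[!tetInside], , drop = FALSE]
  tetAperture <- min_power_cpp(coords, w, tetApex)

  ## vertices: neighbours through edges
  vlist <- data.frame(vert = c(edgeVerts[, 1], edgeVerts[, 2]),
                      other = c(edgeVerts[, 2], edgeVerts[, 1]),
                      edge = rep(seq_len(ne), 2))
  attv <- pw(vlist$other, coords[vlist$vert, , drop = FALSE]) < -w[vlist$vert]
  vertAttached <- .grp_any(attv, vlist$vert, n)
  vcofMin <- .grp_min(edgeAlpha[vlist$edge], vlist$vert, n)
  vertAlpha <- ifelse(vertAttached, vcofMin, -w)
  present <- tabulate(c(edgeVerts), n) > 0
  vertAlpha[!present] <- NA_real_
  vertAttached[!present] <- NA

  tri <- new("RegularTriangulation", structure = s,
             tetVerts = tets, tetCenter = ot$center, tetSize = ot$size,
             tetApex = tetApex, tetAperture = tetAperture,
             tetTris = tetTris,
             triVerts = triVerts, triCenter = otr$center, triSize = otr$size,
             triAttached = triAttached, triAlpha = triAlpha,
             triAperture = triAperture, triApex = triApex,
             triTets = triTets, triHull = triHull,
             edgeVerts = edgeVerts, edgeCenter = oe$center,
             edgeSize = oe$size, edgeAttached = edgeAttached,
             edgeAlpha = edgeAlpha,
             vertAlpha = vertAlpha, vertAttached = vertAttached,
             hidden = as.integer(res$hidden), joggleSeed = usedSeed)
  .check_monotone(tri)
  tri
}

# filtration monotonicity under the face relation, asserted on every build
.check_monotone <- function(tri, tol = 1e-7) {
  t2 <- tri@triTets
  for (j in 1:2) {
    sel <- !is.na(t2[, j])
    if (any(tri@triAlpha[sel] > tri@tetSize[t2[sel, j]] + tol))
      stop("filtration monotonicity violated (triangle > tet)")
  }
  es <- rbind(cbind(tri@triVerts[, 1], tri@triVerts[, 2], seq_len(nrow(tri@triVerts))),
              cbind(tri@triVerts[, 1], tri@triVerts[, 3], seq_len(nrow(tri@triVerts))),
              cbind(tri@triVerts[, 2], tri@triVerts[, 3], seq_len(nrow(tri@triVerts))))
  n <- nrow(tri@structure@atoms)
  eid <- match(.row_key(es[, 1:2, drop = FALSE], n),
               .row_key(tri@edgeVerts, n))
  if (any(tri@edgeAlpha[eid] > tri@triAlpha[es[, 3]] + tol))
    stop("filtration monotonicity violated (edge > triangle)")
  vs <- c(tri@edgeVerts[, 1], tri@edgeVerts[, 2])
  ea <- rep(tri@edgeAlpha, 2)
  if (any(tri@vertAlpha[vs] > ea + tol, na.rm = TRUE))
    stop("filtration monotonicity violated (vertex > edge)")
  invisible(TRUE)
}

#' Alpha complex at a given alpha
#'
#' All simplices with alpha value at most \code{alpha}; closed under taking
#' faces by filtration monotonicity.
#'
#' @param tri a [RegularTriangulation-class].
#' @param alpha growth parameter (A^2); 0 represents the space covered by
#'   the atoms themselves.
#' @return list with integer index vectors \code{tetrahedra},
#'   \code{triangles}, \code{edges}, \code{vertices}.
#' @export
alphaComplex <- function(tri, alpha = 0) {
  list(tetrahedra = which(tri@tetSize <= alpha),
       triangles = which(tri@triAlpha <= alpha),
       edges = which(tri@edgeAlpha <= alpha),
       vertices = which(!is.na(tri@vertAlpha) & tri@vertAlpha <= alpha))
}

# Euclidean volume of tetrahedra, by row of a (m x 4) vertex-index matrix
.tet_volumes <- function(coords, tets) {
  a <- coords[tets[, 1], , drop = FALSE]
  b <- coords[tets[, 2], , drop = FALSE] - a
  c_ <- coords[tets[, 3], , drop = FALSE] - a
  d <- coords[tets[, 4], , drop = FALSE] - a
  abs(b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
      b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
      b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}
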