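# 1D channel profiles: radius, physico-chemical, conservation and
# electrostatic, all parametrized by centerline arc length on [0, d];
# plus Monte-Carlo channel volume from the tetrahedral representation.

.profile <- function(name, t, values, d) {
  # consecutive centerline points can coincide (a tetrahedron apex that
  # falls on its facet's apex); nudge tied positions by a nanometre-scale
  # epsilon so that t is strictly increasing while keeping one sample per
  # simplex
  t <- as.numeric(t)
  for (i in seq_along(t)[-1])
    if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + 1e-9
  new("ChannelProfile", name = name, t = t,
      values = as.numeric(values), d = as.numeric(d))
}

#' Radius profile of a channel
#'
#' The square root of the power distance along the channel: at triangle
#' crossings the orthosphere radius of the three flanking atoms, at
#' tetrahedron nodes the orthosphere radius of the four lining atoms.  Its
#' minimum equals the channel's bottleneck radius.
#'
#' @param ch a [Channel-class].
#' @return a [ChannelProfile-class].
#' @export
radiusProfile <- function(ch) {
  .profile("radius", ch@arc, ch@radii, ch@length)
}

#' Geometric clearance (probe radius) profile
#'
#' The Euclidean distance from each centerline point to the nearest atom
#' ball surface: the radius of the largest spherical probe centred at that
#' point.  This is the HOLE-style convention; it is systematically smaller
#' than the orthosphere radius of [radiusProfile()] (for an atom of radius
#' r at clearance c the orthosphere radius is \eqn{\sqrt{c^2 + 2rc}}).
#'
#' @param ch a [Channel-class].
#' @return a [ChannelProfile-class].
#' @export
clearanceProfile <- function(ch) {
  a <- ch@structure
  pts <- ch@centerline
  val <- vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt((a$x - pts[i, 1])^2 + (a$y - pts[i, 2])^2 +
              (a$z - pts[i, 3])^2) - a$radius
    min(d)
  }, numeric(1))
  .profile("clearance", ch@arc, val, ch@length)
}

# residues of the 4 atoms lining each path tetrahedron
.node_residues <- function(ch) {
  a <- ch@structure
  m <- ch@tetAtoms
  matrix(a$resname[m], nrow = nrow(m))
}

.node_profile_mean <- function(ch, valueOf, name) {
  m <- ch@tetAtoms
  vals <- matrix(valueOf(as.vector(m)), nrow = nrow(m))
  v <- rowMeans(vals, na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_  # all four atoms missing -> flagged sample
  tt <- ch@arc[seq(1, length(ch@arc), by = 2)]
  .profile(name, tt, v, ch@length)
}

#' Physico-chemical profile of a channel
#'
#' Per path tetrahedron, the mean of the scale values of the residues
#' owning its four vertex atoms; atoms of residues absent from the scale
#' are excluded from the mean, and a node whose four residues are all
#' non-standard yields a flagged (NA) sample.
#'
#' @param ch a [Channel-class].
#' @param scale a [ScaleTable-class], e.g. \code{scaleTable("hydropathy")}.
#' @return a [ChannelProfile-class] sampled at the tetrahedron nodes.
#' @export
physchemProfile <- function(ch, scale) {
  a <- ch@structure
  .node_profile_mean(ch, function(idx)
    unname(scale@values[a$resname[idx]]), scale@name)
}

#' Conservation profile of a channel
#'
#' Per path tetrahedron, the mean conservation score of the four residues
#' incident on it; residues missing from the table are excluded from the
#' mean.
#'
#' @param ch a [Channel-class].
#' @param tab a [ConservationTable-class].
#' @return a [ChannelProfile-class] sampled at the tetrahedron nodes.
#' @export
conservationProfile <- function(ch, tab) {
  a <- ch@structure
  .node_profile_mean(ch, function(idx)
    conservationScore(tab, a$chain[idx], a$resno[idx]), "conservation")
}

#' Shipped residue scale tables
#'
#' \itemize{
#'   \item \code{hydropathy}: Kyte--Doolittle hydropathy.
#'   \item \code{charge}: unit residue charge (Asp/Glu -1, Lys/Arg +1,
#'     His +0.5, others 0).
#'   \item \code{bulkiness}: Zimmerman bulkiness.
#' }
#' Tables are plain TSV files under \code{extdata/scales} and may be
#' replaced by the user via [readScaleTable()].
#'
#' @param name one of "hydropathy", "charge", "bulkiness".
#' @return a [ScaleTable-class].
#' @export
scaleTable <- function(name = c("hydropathy", "charge", "bulkiness")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                      package = "AlphaPore", mustWork = TRUE)
  readScaleTable(path, name = name)
}

#' Read a residue scale table from TSV
#'
#' Rows of \code{residue value}; must cover the 20 standard residues.
#'
#' @param path TSV file.
#' @param name label.
#' @return a [ScaleTable-class].
#' @export
readScaleTable <- function(path, name = basename(path)) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("resname", "value"),
                          stringsAsFactors = FALSE)
  new("ScaleTable", name = name,
      values = stats::setNames(df$value, toupper(df$resname)))
}

#' Read an OpenDX scalar grid (APBS output)
#'
#' Parses the regular-grid OpenDX dialect written by APBS: gridpositions
#' counts, origin, three axis-aligned delta rows, then the data stream with
#' the z index varying fastest.  Non-orthogonal deltas are rejected.
#'
#' @param path .dx file.
#' @return a [ScalarGrid-class].
#' @export
readOpenDX <- function(path) {
  lines <- readLines(path)
  cl <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(cl) == 0) stop("not an OpenDX gridpositions file", call. = FALSE)
  dims <- as.integer(utils::tail(strsplit(trimws(cl[1]), "\\s+")[[1]], 3))
  org <- grep("^\\s*origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(org[1]), "\\s+")[[1]][2:4])
  dl <- grep("^\\s*delta", lines, value = TRUE)
  if (length(dl) < 3) stop("missing delta rows", call. = FALSE)
  D <- t(vapply(dl[1:3], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4]), numeric(3)))
  if (any(abs(D[upper.tri(D)]) > 1e-12) || any(abs(D[lower.tri(D)]) > 1e-12))
    stop("non-orthogonal grid axes are not supported", call. = FALSE)
  spacing <- diag(D)
  start <- grep("data follows", lines)
  if (length(start) == 0) stop("missing data section", call. = FALSE)
  end <- grep("^\\s*(attribute|object\\s+\"|component)", lines)
  end <- end[end > start[1]]
  end <- if (length(end) > 0) min(end) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(start[1] + 1):end]),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop("value count does not match grid dims", call. = FALSE)
  # APBS writes with z fastest: vals index = ((i-1)*ny + (j-1))*nz + k
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  new("ScalarGrid", origin = origin, spacing = spacing, dims = dims,
      values = arr)
}

#' Trilinear interpolation of a scalar grid
#'
#' Exact for trilinear fields; errors if a query point falls outside the
#' grid bounds, naming the point.
#'
#' @param grid a [ScalarGrid-class].
#' @param pts n x 3 matrix of query points.
#' @return numeric vector of interpolated values.
#' @export
interpolateGrid <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  u <- sweep(sweep(pts, 2, grid@origin), 2, grid@spacing, "/")
  hi <- grid@dims - 1L
  out <- numeric(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    if (any(u[r, ] < -1e-9) || any(u[r, ] > hi + 1e-9))
      stop(sprintf("point (%.3f, %.3f, %.3f) outside grid bounds",
                   pts[r, 1], pts[r, 2], pts[r, 3]), call. = FALSE)
    i0 <- pmin(pmax(floor(u[r, ]), 0), hi - 1L)
    fr <- u[r, ] - i0
    i0 <- as.integer(i0) + 1L  # R indexing
    v <- grid@values
    c00 <- v[i0[1], i0[2], i0[3]] * (1 - fr[1]) +
      v[i0[1] + 1, i0[2], i0[3]] * fr[1]
    c10 <- v[i0[1], i0[2] + 1, i0[3]] * (1 - fr[1]) +
      v[i0[1] + 1, i0[2] + 1, i0[3]] * fr[1]
    c01 <- v[i0[1], i0[2], i0[3] + 1] * (1 - fr[1]) +
      v[i0[1] + 1, i0[2], i0[3] + 1] * fr[1]
    c11 <- v[i0[1], i0[2] + 1, i0[3] + 1] * (1 - fr[1]) +
      v[i0[1] + 1, i0[2] + 1, i0[3] + 1] * fr[1]
    c0 <- c00 * (1 - fr[2]) + c10 * fr[2]
    c1 <- c01 * (1 - fr[2]) + c11 * fr[2]
    out[r] <- c0 * (1 - fr[3]) + c1 * fr[3]
  }
  out
}

#' Electrostatic potential profile
#'
#' Trilinear interpolation of a potential grid (e.g. APBS OpenDX output) at
#' every centerline point.
#'
#' @param ch a [Channel-class].
#' @param grid a [ScalarGrid-class].
#' @return a [ChannelProfile-class].
#' @export
electrostaticProfile <- function(ch, grid) {
  .profile("electrostatic", ch@arc, interpolateGrid(grid, ch@centerline),
           ch@length)
}

#' Monte-Carlo channel volume
#'
#' The tetrahedral representation gives the channel volume as the sum over
#' path tetrahedra of the tetrahedron volume minus the part covered by any
#' atom ball, estimated by uniform sampling inside each tetrahedron.
#'
#' @param ch a [Channel-class].
#' @param mcSamples total sample count (>= 1000).
#' @param seed RNG seed (deterministic result).
#' @return list with \code{volume} and \code{stderr} (A^3).
#' @export
channelVolume <- function(ch, mcSamples = 20000L, seed = 1L) {
  if (mcSamples < 1000) stop("mcSamples must be >= 1000", call. = FALSE)
  a <- ch@structure
  tets <- ch@tetAtoms
  P <- cbind(a$x, a$y, a$z)
  vol <- .tet_volumes(P, tets)
  tot <- sum(vol)
  if (tot == 0) return(list(volume = 0, stderr = 0))
  nper <- pmax(50L, as.integer(round(mcSamples * vol / tot)))
  .with_seed(seed, {
    est <- 0
    var <- 0
    for (i in seq_len(nrow(tets))) {
      v <- tets[i, ]
      # uniform barycentric samples via sorted uniforms
      u <- matrix(stats::runif(3 * nper[i]), ncol = 3)
      u <- t(apply(u, 1, sort))
      b <- cbind(u[, 1], u[, 2] - u[, 1], u[, 3] - u[, 2], 1 - u[, 3])
      pts <- b %*% P[v, , drop = FALSE]
      # only balls that can reach the tetrahedron matter
      ctr <- colMeans(P[v, , drop = FALSE])
      reach <- sqrt(max(rowSums(sweep(P[v, , drop = FALSE], 2, ctr)^2))) +
        max(a$radius)
      near <- which((a$x - ctr[1])^2 + (a$y - ctr[2])^2 +
                      (a$z - ctr[3])^2 <= reach^2)
      free <- rep(TRUE, nper[i])
      for (j in near) {
        d2 <- (pts[, 1] - a$x[j])^2 + (pts[, 2] - a$y[j])^2 +
          (pts[, 3] - a$z[j])^2
        free <- free & d2 > a$radius[j]^2
        if (!any(free)) break
      }
      p <- mean(free)
      est <- est + vol[i] * p
      var <- var + vol[i]^2 * p * (1 - p) / nper[i]
    }
    list(volume = est, stderr = sqrt(var))
  })
}

#' Write a profile as CSV
#' @param p a [ChannelProfile-class].
#' @param path output file.
#' @export
writeProfileCSV <- function(p, path) {
  utils::write.csv(data.frame(t = p@t, value = p@values), path,
                   row.names = FALSE)
  invisible(path)
}
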