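# Transmembrane pore extraction and ranking.  The membrane is a user-given
# slab (two parallel planes); structures are assumed pre-oriented (OPM
# convention: membrane normal along z, offsets symmetric about the origin
# are typical but not required).

#' Membrane slab
#'
#' @param lower,upper signed offsets along the normal (A), lower < upper.
#' @param normal membrane normal (defaults to the z axis); normalised.
#' @return a [MembraneSlab-class].
#' @export
membraneSlab <- function(lower = -15, upper = 15, normal = c(0, 0, 1)) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("normal must be non-zero", call. = FALSE)
  new("MembraneSlab", normal = normal / nrm, lower = lower, upper = upper)
}

#' Classify boundary representatives by membrane side
#'
#' Projects each node position on the membrane normal: below the lower
#' plane is B_in, above the upper plane is B_out, otherwise B_mem.  The
#' three sets are disjoint and cover the classified representatives.
#'
#' @param endpoints an [EndpointSet-class].
#' @param net the [ChannelNetwork-class] the endpoints refer to.
#' @param slab a [MembraneSlab-class]; required.
#' @return list with integer vectors \code{Bin}, \code{Bout}, \code{Bmem}.
#' @export
classifyBoundary <- function(endpoints, net, slab) {
  if (missing(slab) || is.null(slab))
    stop("transmembrane mode requires a membrane slab", call. = FALSE)
  b <- endpoints@bImp
  idx <- match(b, net@nodes$tet)
  if (anyNA(idx)) stop("endpoint nodes missing from network", call. = FALSE)
  proj <- as.matrix(net@nodes[idx, c("x", "y", "z")]) %*% slab@normal
  list(Bin = b[proj < slab@lower],
       Bout = b[proj > slab@upper],
       Bmem = b[proj >= slab@lower & proj <= slab@upper])
}

.resample_polyline <- function(pts, n) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 0)
  pts <- pts[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  tt <- seq(0, arc[length(arc)], length.out = n)
  cbind(stats::approx(arc, pts[, 1], xout = tt)$y,
        stats::approx(arc, pts[, 2], xout = tt)$y,
        stats::approx(arc, pts[, 3], xout = tt)$y)
}

# boxcar smoothing of a polyline with a window that shrinks symmetrically
# toward the ends, so the endpoints stay anchored
.smooth_polyline <- function(pts, k) {
  n <- nrow(pts)
  if (k < 1 || n < 3) return(pts)
  out <- pts
  for (i in seq_len(n)) {
    h <- min(k, i - 1L, n - i)
    if (h > 0) out[i, ] <- colMeans(pts[(i - h):(i + h), , drop = FALSE])
  }
  out
}

#' Resample a channel centerline at uniform arc-length spacing
#'
#' The raw tetrahedron-dual centerline winds through wedge fans of the
#' triangulation at sub-Angstrom scale; that winding is discretization
#' noise, not channel geometry.  The centerline is therefore first
#' resampled finely, smoothed with a boxcar of half-width
#' \code{smoothWindow} (in A of arc length; endpoints stay anchored), and
#' then sampled at arc lengths 0, h, 2h, ..., d with h adjusted so the
#' last sample lands exactly on the endpoint.  With \code{smoothWindow =
#' 0} the samples lie exactly on the original polyline.
#'
#' @param ch a [Channel-class] (or a polyline matrix).
#' @param spacing target spacing (A), default 1.
#' @param maxSamples cap on the sample count.
#' @param smoothWindow smoothing half-width (A); default 3, about one atom
#'   diameter.
#' @return list with \code{samples} (m x 3 matrix), \code{spacing}
#'   (arc-length spacing actually used) and \code{arc} (positions).
#' @export
resamplePath <- function(ch, spacing = 1, maxSamples = 512L,
                         smoothWindow = 3) {
  pts <- if (is(ch, "Channel")) ch@centerline else as.matrix(ch)
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 0)
  pts <- pts[keep, , drop = FALSE]
  if (smoothWindow > 0) {
    h0 <- 0.25
    seg <- sqrt(rowSums(diff(pts)^2))
    nf <- max(8L, min(4096L, ceiling(sum(seg) / h0) + 1L))
    fine <- .resample_polyline(pts, nf)
    pts <- .smooth_polyline(fine, max(1L, round(smoothWindow / h0)))
  }
  seg <- sqrt(rowSums(diff(pts)^2))
  L <- sum(seg)
  if (L <= 2 * spacing)
    stop("degenerate path: centerline shorter than twice the spacing",
         call. = FALSE)
  nseg <- min(max(4L, round(L / spacing)), maxSamples - 1L)
  h <- L / nseg
  tt <- seq(0, L, length.out = nseg + 1L)
  arc <- c(0, cumsum(seg))
  out <- cbind(stats::approx(arc, pts[, 1], xout = tt)$y,
               stats::approx(arc, pts[, 2], xout = tt)$y,
               stats::approx(arc, pts[, 3], xout = tt)$y)
  list(samples = out, spacing = h, arc = tt)
}

#' Largest probe that can follow a channel's (smoothed) axis
#'
#' Resamples the smoothed centerline densely and returns the minimum
#' clearance (distance to the nearest atom ball surface) over the
#' samples: the radius of the largest spherical probe that can traverse
#' the channel along its axis.
#'
#' @param ch a [Channel-class].
#' @param spacing sample spacing (A).
#' @param smoothWindow see [resamplePath()].
#' @return probe radius (A).
#' @export
traversalProbeRadius <- function(ch, spacing = 0.5, smoothWindow = 3) {
  S <- resamplePath(ch, spacing = spacing, smoothWindow = smoothWindow,
                    maxSamples = 2048L)$samples
  a <- ch@structure
  min(vapply(seq_len(nrow(S)), function(i) {
    min(sqrt((a$x - S[i, 1])^2 + (a$y - S[i, 2])^2 +
             (a$z - S[i, 3])^2) - a$radius)
  }, numeric(1)))
}

#' Multi-scale straightness of a resampled path
#'
#' \deqn{s(S) = \frac{\sum_{d=1}^{\lfloor|S|/2\rfloor} \sum_{i=1}^{|S|-2d}
#'   d \cos\angle(S_i, S_{i+d}, S_{i+2d})}
#'   {\sum_{d=1}^{\lfloor|S|/2\rfloor} \sum_{i=1}^{|S|-2d} d}}
#'
#' where the cosine is taken of the \emph{turning} angle between the
#' direction vectors \eqn{S_{i+d}-S_i} and \eqn{S_{i+2d}-S_{i+d}}, so a
#' perfectly straight path scores exactly 1 and s lies in [-1, 1].  The
#' scale d runs from adjacent samples to half the path, capturing average
#' curvature at all scales.
#'
#' @param samples m x 3 matrix of uniformly spaced samples (m >= 5), e.g.
#'   \code{resamplePath(ch)$samples}.
#' @return straightness in [-1, 1].
#' @export
straightness <- function(samples) {
  S <- as.matrix(samples)
  m <- nrow(S)
  if (m < 5) stop("need at least 5 samples", call. = FALSE)
  num <- 0
  den <- 0
  for (d in seq_len(m %/% 2)) {
    n_i <- m - 2 * d
    if (n_i < 1) break
    i <- seq_len(n_i)
    u <- S[i + d, , drop = FALSE] - S[i, , drop = FALSE]
    v <- S[i + 2 * d, , drop = FALSE] - S[i + d, , drop = FALSE]
    nu <- sqrt(rowSums(u^2))
    nv <- sqrt(rowSums(v^2))
    if (any(nu == 0) || any(nv == 0))
      stop("degenerate path: coincident samples", call. = FALSE)
    cosang <- rowSums(u * v) / (nu * nv)
    cosang <- pmin(1, pmax(-1, cosang))
    num <- num + d * sum(cosang)
    den <- den + d * n_i
  }
  num / den
}

#' Score and rank transmembrane pores
#'
#' \deqn{f(x) = \frac13\left(\frac{|x|}{\max_y |y|} +
#'   \frac{bn(x)}{\max_y bn(y)} + s(x)\right)}
#'
#' with |x| the pore length, bn(x) the bottleneck radius (min orthosphere
#' radius along the path) and s(x) the straightness of the resampled
#' centerline.  Pores are returned sorted by decreasing score; the first is
#' the best transmembrane pore.
#'
#' @param pores list of [Channel-class].
#' @param spacing resampling spacing for s(x) (A).
#' @return list of scored [Channel-class], sorted by decreasing score.
#' @export
rankTMPores <- function(pores, spacing = 1) {
  if (length(pores) == 0) return(pores)
  len <- vapply(pores, function(p) p@length, numeric(1))
  bn <- vapply(pores, function(p) p@bottleneckRadius, numeric(1))
  s <- vapply(pores, function(p)
    straightness(resamplePath(p, spacing = spacing)$samples), numeric(1))
  f <- (len / max(len) + bn / max(bn) + s) / 3
  pores <- lapply(seq_along(pores), function(i) {
    p <- pores[[i]]
    p@straightness <- s[i]
    p@score <- f[i]
    p@kind <- "transmembrane"
    p
  })
  pores[order(-f)]
}

#' Extract and rank transmembrane pores
#'
#' Classifies the boundary representatives by the membrane slab, extracts a
#' shortest-cost pore for every B_in x B_out pair, collapses identical
#' paths, and ranks by the transmembrane score.
#'
#' @param net a pruned [ChannelNetwork-class].
#' @param endpoints an [EndpointSet-class].
#' @param slab a [MembraneSlab-class].
#' @param spacing resampling spacing for the straightness term (A).
#' @return list of scored [Channel-class], best first (empty when no
#'   in/out pair is connected).
#' @export
transmembranePores <- function(net, endpoints, slab, spacing = 1) {
  cls <- classifyBoundary(endpoints, net, slab)
  if (length(cls$Bin) == 0 || length(cls$Bout) == 0) return(list())
  out <- list()
  seen <- character(0)
  for (a in cls$Bin) {
    for (b in cls$Bout) {
      ch <- tryCatch(shortestChannel(net, a, b, kind = "transmembrane"),
                     error = function(e) NULL)
      if (is.null(ch)) next
      key <- paste(sort(ch@triPath), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- ch
    }
  }
  rankTMPores(out, spacing = spacing)
}

#' Write a transmembrane pore report as CSV
#'
#' @param pores scored pores from [transmembranePores()].
#' @param path output file.
#' @export
writeTMReport <- function(pores, path) {
  df <- data.frame(rank = seq_along(pores),
                   length = vapply(pores, function(p) p@length, numeric(1)),
                   bottleneck_radius = vapply(pores, function(p)
                     p@bottleneckRadius, numeric(1)),
                   straightness = vapply(pores, function(p)
                     p@straightness, numeric(1)),
                   score = vapply(pores, function(p) p@score, numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
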