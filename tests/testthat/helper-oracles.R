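# Independent oracles used throughout the suite.  Everything here is
# deliberately naive (enumeration, direct formula transcription, dense
# sampling) and shares no code path with the package internals.

rand_structure <- function(n, seed, weighted = TRUE, box = 10) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
  r <- if (weighted) runif(n, 0.4, 1.6) else rep(1e-4, n)
  df <- data.frame(serial = seq_len(n), element = "C", name = "C",
                   resname = "UNK", resno = seq_len(n), chain = "A",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   radius = r, weight = r^2, stringsAsFactors = FALSE)
  weightedStructure(df, id = sprintf("rand%d_%d", n, seed))
}

# vectorized 3x3 determinant from row triples
.det3rows <- function(a1, a2, a3, b1, b2, b3, c1, c2, c3) {
  a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
    a3 * (b1 * c2 - b2 * c1)
}

# brute-force regular triangulation: enumerate all 4-subsets, accept those
# whose orthosphere has power >= its size to every other point
brute_rt <- function(coords, w, tol = 1e-7) {
  n <- nrow(coords)
  cmb <- t(utils::combn(n, 4))
  l <- rowSums(coords^2) - w
  p1 <- coords[cmb[, 1], , drop = FALSE]
  A1 <- 2 * (coords[cmb[, 2], , drop = FALSE] - p1)
  A2 <- 2 * (coords[cmb[, 3], , drop = FALSE] - p1)
  A3 <- 2 * (coords[cmb[, 4], , drop = FALSE] - p1)
  b1 <- l[cmb[, 2]] - l[cmb[, 1]]
  b2 <- l[cmb[, 3]] - l[cmb[, 1]]
  b3 <- l[cmb[, 4]] - l[cmb[, 1]]
  det <- .det3rows(A1[, 1], A1[, 2], A1[, 3], A2[, 1], A2[, 2], A2[, 3],
                   A3[, 1], A3[, 2], A3[, 3])
  cx <- .det3rows(b1, A1[, 2], A1[, 3], b2, A2[, 2], A2[, 3],
                  b3, A3[, 2], A3[, 3]) / det
  cy <- .det3rows(A1[, 1], b1, A1[, 3], A2[, 1], b2, A2[, 3],
                  A3[, 1], b3, A3[, 3]) / det
  cz <- .det3rows(A1[, 1], A1[, 2], b1, A2[, 1], A2[, 2], b2,
                  A3[, 1], A3[, 2], b3) / det
  size <- (cx - p1[, 1])^2 + (cy - p1[, 2])^2 + (cz - p1[, 3])^2 -
    w[cmb[, 1]]
  ok <- is.finite(det) & abs(det) > 1e-9
  # power of every point to every candidate orthosphere
  P <- outer(cx, coords[, 1], "-")^2 + outer(cy, coords[, 2], "-")^2 +
    outer(cz, coords[, 3], "-")^2
  P <- sweep(P, 2, w)
  P[cbind(rep(seq_len(nrow(cmb)), 4), as.vector(cmb))] <- Inf
  minP <- do.call(pmin, lapply(seq_len(n), function(j) P[, j]))
  keep <- ok & (minP >= size - tol)
  m <- cmb[keep, , drop = FALSE]
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

tet_key <- function(m) apply(m, 1, paste, collapse = ",")

# dense-sampling dual-complex membership at alpha = 0: a simplex is in the
# complex iff the balls and power cells of its vertices share a point.
# The equal-power locus of the vertex set is an affine subspace; we sample
# it densely.  Returns "in", "out" or "unclear" (sampling cannot certify).
dual_member_sample <- function(coords, w, verts, step = 0.08, delta = 0.05) {
  k <- length(verts)
  p <- coords[verts, , drop = FALSE]
  l <- rowSums(p^2) - w[verts]
  if (k > 1) {
    A <- 2 * sweep(p[-1, , drop = FALSE], 2, p[1, ])
    b <- l[-1] - l[1]
    sv <- svd(A, nu = nrow(A), nv = 3)
    pos <- which(sv$d > 1e-9)
    x0 <- c(sv$v[, pos, drop = FALSE] %*%
              ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
    nullIdx <- setdiff(seq_len(3), pos)
    nullB <- sv$v[, nullIdx, drop = FALSE]
    nd <- length(nullIdx)
  } else {
    x0 <- p[1, ]
    nullB <- diag(3)
    nd <- 3
  }
  # centre the sampling grid near the defining atoms (the least-norm
  # solution can sit far from the molecule)
  if (nd > 0 && nd < 3) {
    ctr <- colMeans(p)
    x0 <- x0 + c(nullB %*% (t(nullB) %*% (ctr - x0)))
  }
  R <- max(4, sqrt(max(abs(w))) + 2)
  grid1 <- seq(-R, R, by = step)
  samples <- switch(as.character(nd),
    "0" = matrix(x0, nrow = 1),
    "1" = t(vapply(grid1, function(t) x0 + t * nullB[, 1], numeric(3))),
    "2" = {
      g <- as.matrix(expand.grid(grid1, grid1))
      t(apply(g, 1, function(t) x0 + t[1] * nullB[, 1] + t[2] * nullB[, 2]))
    },
    "3" = {
      g <- as.matrix(expand.grid(grid1, grid1, grid1))
      sweep(g %*% t(nullB), 2, -x0)
    })
  others <- setdiff(seq_len(nrow(coords)), verts)
  pwv <- rowSums(sweep(samples, 2, p[1, ])^2) - w[verts[1]]
  if (length(others) > 0) {
    minO <- rep(Inf, nrow(samples))
    for (j in others) {
      pj <- rowSums(sweep(samples, 2, coords[j, ])^2) - w[j]
      minO <- pmin(minO, pj)
    }
  } else minO <- rep(Inf, nrow(samples))
  strict <- any(pwv <= -delta & pwv <= minO - delta)
  loose <- any(pwv <= delta & pwv <= minO + delta)
  if (strict) "in" else if (!loose) "out" else "unclear"
}

# --- graph oracles -------------------------------------------------------

rand_graph_network <- function(n, seed, pExtra = 0.4) {
  set.seed(seed)
  # random connected graph: spanning tree + extra edges
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1),
                             integer(1)))
  extra <- t(utils::combn(n, 2))
  extra <- extra[runif(nrow(extra)) < pExtra, , drop = FALSE]
  em <- unique(rbind(cbind(pmin(edges[, 1], edges[, 2]),
                           pmax(edges[, 1], edges[, 2])),
                     extra))
  ne <- nrow(em)
  pos <- matrix(runif(3 * n, 0, 10), ncol = 3)
  edf <- data.frame(tri = seq_len(ne), from = em[, 1], to = em[, 2],
                    length = runif(ne, 0.5, 4), width = runif(ne, 0.5, 5))
  # one exterior edge so depths are defined
  edf <- rbind(edf, data.frame(tri = ne + 1L, from = 1L, to = 0L,
                               length = 1, width = 1))
  ndf <- data.frame(tet = seq_len(n), x = pos[, 1], y = pos[, 2],
                    z = pos[, 3], width = runif(n, 1, 5))
  assembleNetwork(ndf, edf)
}

all_simple_paths_costs <- function(net, src, dst) {
  e <- networkEdges(net)
  e <- e[e$to != 0, ]
  adj <- lapply(networkNodes(net)$tet, function(v) {
    rows <- which(e$from == v | e$to == v)
    data.frame(other = ifelse(e$from[rows] == v, e$to[rows], e$from[rows]),
               cost = e$cost[rows], width = e$width[rows])
  })
  names(adj) <- networkNodes(net)$tet
  out <- list()
  walk <- function(v, visited, cost, minw) {
    if (v == dst) {
      out[[length(out) + 1L]] <<- c(cost = cost, minw = minw)
      return(invisible())
    }
    a <- adj[[as.character(v)]]
    for (i in seq_len(nrow(a))) {
      u <- a$other[i]
      if (u %in% visited) next
      walk(u, c(visited, u), cost + a$cost[i], min(minw, a$width[i]))
    }
  }
  walk(src, src, 0, Inf)
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

bellman_ford_cost <- function(net, src, dst) {
  e <- networkEdges(net)
  e <- e[e$to != 0, ]
  nodes <- networkNodes(net)$tet
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[as.character(src)] <- 0
  for (iter in seq_len(length(nodes))) {
    nd <- pmin(d, stats::setNames(rep(Inf, length(nodes)), nodes))
    for (i in seq_len(nrow(e))) {
      a <- as.character(e$from[i]); b <- as.character(e$to[i])
      nd[b] <- min(nd[b], d[a] + e$cost[i])
      nd[a] <- min(nd[a], d[b] + e$cost[i])
    }
    if (all(nd == d)) break
    d <- nd
  }
  unname(d[as.character(dst)])
}

# naive transcription of the multi-scale straightness double sum
straightness_naive <- function(S) {
  m <- nrow(S)
  num <- 0; den <- 0
  for (d in seq_len(floor(m / 2))) {
    for (i in seq_len(m - 2 * d)) {
      u <- S[i + d, ] - S[i, ]
      v <- S[i + 2 * d, ] - S[i + d, ]
      cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      num <- num + d * cosang
      den <- den + d
    }
  }
  num / den
}

# --- shared expensive fixtures ------------------------------------------

.fixtures <- new.env(parent = emptyenv())

tube_fixture <- function() {
  if (is.null(.fixtures$tube)) {
    tube <- makeTube()
    tri <- regularTriangulation(tube)
    net <- channelNetwork(tri)
    eps <- selectEndpoints(net, k = 10)
    tm <- transmembranePores(net, eps, membraneSlab(10, 30))
    .fixtures$tube <- list(structure = tube, tri = tri, net = net,
                           eps = eps, tm = tm)
  }
  .fixtures$tube
}

barrel_fixture <- function() {
  if (is.null(.fixtures$barrel)) {
    b <- makeBarrel(nPores = 2)
    tri <- regularTriangulation(b)
    net <- channelNetwork(tri)
    eps <- selectEndpoints(net, k = 10)
    pores <- importantPores(net, eps)
    .fixtures$barrel <- list(structure = b, tri = tri, net = net,
                             eps = eps, pores = pores)
  }
  .fixtures$barrel
}
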