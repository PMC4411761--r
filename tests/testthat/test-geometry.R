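test_that("power distance matches its definition", {
  expect_equal(powerDistance(c(0, 0, 0), 1, c(2, 0, 0)), 3)
  # zero exactly on the ball surface
  expect_equal(powerDistance(c(1, 2, 3), 2.25, c(1, 2, 3) + c(1.5, 0, 0)), 0)
  set.seed(11)
  for (i in 1:20) {
    ctr <- runif(3, -5, 5); w <- runif(1, 0.1, 4); x <- runif(3, -5, 5)
    expect_equal(powerDistance(ctr, w, x), sum((x - ctr)^2) - w)
  }
  # vectorized over rows
  X <- matrix(runif(9), 3)
  expect_equal(powerDistance(c(0, 0, 0), 1, X), rowSums(X^2) - 1)
})

test_that("orthosphere reproduces closed forms and zero-power equations", {
  # regular tetrahedron, edge 2, radii 1: centre = centroid,
  # size = (a sqrt(6)/4)^2 - 1 = 6/4 - 1
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(2)
  o <- orthosphere(v, rep(1, 4))
  expect_equal(o$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(o$size, 0.5, tolerance = 1e-12)

  # equilateral triangle, zero weights: circumcentre + squared circumradius
  tr <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  o <- orthosphere(tr, rep(0, 3))
  expect_equal(o$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(o$size, 1, tolerance = 1e-12)

  # random weighted tuples satisfy the zero-power equations
  set.seed(7)
  for (k in c(2, 3, 4)) {
    for (rep in 1:15) {
      ctrs <- matrix(runif(3 * k, 0, 5), ncol = 3)
      w <- runif(k, 0.1, 2)
      o <- orthosphere(ctrs, w)
      pw <- rowSums(sweep(ctrs, 2, o$center)^2) - w
      expect_equal(pw, rep(o$size, k), tolerance = 1e-8)
    }
  }
  expect_error(orthosphere(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           rep(1, 3)), "degenerate")
})

test_that("four affinely independent points give one tetrahedron", {
  s <- weightedStructure(AlphaPore:::.synth_frame(
    rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4)), 1))
  tr <- regularTriangulation(s)
  expect_equal(nrow(tetrahedra(tr)), 1L)
  expect_equal(sum(tr@triHull), 4L)
  expect_equal(nrow(tr@triVerts), 4L)
  expect_equal(nrow(tr@edgeVerts), 6L)
})

test_that("triangulation of unweighted points equals brute-force Delaunay", {
  s <- rand_structure(50, seed = 101, weighted = FALSE)
  tr <- regularTriangulation(s)
  coords <- as.matrix(atoms(s)[, c("x", "y", "z")])
  oracle <- brute_rt(coords, atoms(s)$weight)
  impl <- t(apply(tetrahedra(tr), 1, sort))
  expect_setequal(tet_key(impl), tet_key(oracle))
})

test_that("dominated atoms are hidden from the triangulation", {
  set.seed(3)
  xyz <- rbind(matrix(runif(30, 0, 10), ncol = 3),
               c(5, 5, 5),        # big ball
               c(5.2, 5, 5))      # dominated neighbour
  r <- c(runif(10, 0.5, 1), 4, 0.2)
  df <- AlphaPore:::.synth_frame(xyz, 1)
  df$radius <- r; df$weight <- r^2
  tr <- regularTriangulation(weightedStructure(df))
  expect_true(12L %in% tr@hidden)
  expect_false(12L %in% as.vector(tetrahedra(tr)))
  # oracle: the dominated point is in no empty-orthosphere tetrahedron
  oracle <- brute_rt(xyz, r^2)
  expect_false(12L %in% as.vector(oracle))
})

test_that("equal weights reproduce the unweighted triangulation with a shifted filtration", {
  s0 <- rand_structure(40, seed = 55, weighted = FALSE)
  a <- atoms(s0)
  a$radius <- 1.7; a$weight <- 1.7^2
  s1 <- weightedStructure(a, id = "shifted")
  t0 <- regularTriangulation(s0)
  t1 <- regularTriangulation(s1)
  k0 <- tet_key(tetrahedra(t0)); k1 <- tet_key(tetrahedra(t1))
  expect_setequal(k0, k1)
  # sizes shift by the common weight
  m <- match(k1, k0)
  expect_equal(t1@tetSize, t0@tetSize[m] - (1.7^2 - 1e-8), tolerance = 1e-4)
})

test_that("empty-orthosphere property holds against all atoms", {
  for (seed in c(21, 22)) {
    s <- rand_structure(120, seed = seed)
    tr <- regularTriangulation(s)
    a <- atoms(s)
    coords <- as.matrix(a[, c("x", "y", "z")])
    P <- outer(tr@tetCenter[, 1], coords[, 1], "-")^2 +
      outer(tr@tetCenter[, 2], coords[, 2], "-")^2 +
      outer(tr@tetCenter[, 3], coords[, 3], "-")^2
    P <- sweep(P, 2, a$weight)
    P[cbind(rep(seq_len(nrow(tr@tetVerts)), 4), as.vector(tr@tetVerts))] <- Inf
    minP <- apply(P, 1, min)
    expect_true(all(minP >= tr@tetSize - 1e-6))
  }
})

test_that("tetrahedra tile the convex hull", {
  s <- rand_structure(80, seed = 9)
  tr <- regularTriangulation(s)
  coords <- as.matrix(atoms(s)[, c("x", "y", "z")])
  tetVol <- sum(AlphaPore:::.tet_volumes(coords, tetrahedra(tr)))
  # hull volume via the divergence theorem over outward-oriented hull
  # facets (outward = away from the incident tetrahedron's 4th vertex)
  h <- which(tr@triHull)
  vol <- 0
  for (i in h) {
    v <- tr@triVerts[i, ]
    tet <- tr@triTets[i, 1]
    d <- setdiff(tr@tetVerts[tet, ], v)
    a <- coords[v[1], ]; b <- coords[v[2], ]; cc <- coords[v[3], ]
    orient <- det(rbind(b - a, cc - a, coords[d, ] - a))
    sgn <- if (orient > 0) -1 else 1   # make the normal outward
    vol <- vol + sgn * det(rbind(a, b, cc)) / 6
  }
  expect_equal(tetVol, abs(vol), tolerance = 1e-6)
})

test_that("pair-distance edges enter the alpha complex per the size formula", {
  # two atoms radius 1 at distance d: edge size = (d/2)^2 - 1
  mk <- function(d) {
    base <- rbind(c(0, 0, 0), c(d, 0, 0), c(30, 40, 0), c(30, 0, 40),
                  c(-30, -20, 10))
    df <- AlphaPore:::.synth_frame(base, 1)
    weightedStructure(df)
  }
  tr <- regularTriangulation(mk(1.9))
  e <- which(tr@edgeVerts[, 1] == 1 & tr@edgeVerts[, 2] == 2)
  expect_length(e, 1L)
  expect_equal(tr@edgeSize[e], 0.95^2 - 1, tolerance = 1e-6)
  expect_false(tr@edgeAttached[e])  # far-away cofaces cannot attach it
  expect_lte(tr@edgeAlpha[e], 0)    # in the complex at alpha = 0

  tr2 <- regularTriangulation(mk(2.2))
  e2 <- which(tr2@edgeVerts[, 1] == 1 & tr2@edgeVerts[, 2] == 2)
  expect_equal(tr2@edgeSize[e2], 1.1^2 - 1, tolerance = 1e-6)
  expect_gt(tr2@edgeAlpha[e2], 0)   # not in the complex at alpha = 0
})

test_that("alpha complex membership matches the sampled dual complex", {
  agree <- 0L; checked <- 0L
  for (seed in c(31, 32, 33, 34)) {
    set.seed(seed)
    n <- sample(6:8, 1)
    xyz <- matrix(runif(3 * n, 0, 6), ncol = 3)
    r <- runif(n, 0.8, 1.8)
    df <- AlphaPore:::.synth_frame(xyz, 1)
    df$radius <- r; df$weight <- r^2
    tr <- regularTriangulation(weightedStructure(df))
    cx <- alphaComplex(tr, 0)
    for (i in seq_len(nrow(tr@triVerts))) {
      verdict <- dual_member_sample(xyz, r^2, tr@triVerts[i, ])
      if (verdict == "unclear") next
      checked <- checked + 1L
      expect_equal(verdict == "in", i %in% cx$triangles,
                   info = sprintf("seed %d triangle %d", seed, i))
      agree <- agree + 1L
    }
    for (i in seq_len(nrow(tr@edgeVerts))) {
      verdict <- dual_member_sample(xyz, r^2, tr@edgeVerts[i, ])
      if (verdict == "unclear") next
      checked <- checked + 1L
      expect_equal(verdict == "in", i %in% cx$edges,
                   info = sprintf("seed %d edge %d", seed, i))
    }
  }
  expect_gt(checked, 20)  # the oracle must certify a useful fraction
})

test_that("alpha complex is monotone in alpha with the right extremes", {
  s <- rand_structure(30, seed = 77)
  tr <- regularTriangulation(s)
  expect_equal(lengths(alphaComplex(tr, -Inf)),
               c(tetrahedra = 0L, triangles = 0L, edges = 0L, vertices = 0L),
               ignore_attr = TRUE)
  full <- alphaComplex(tr, Inf)
  expect_equal(length(full$tetrahedra), nrow(tetrahedra(tr)))
  expect_equal(length(full$triangles), nrow(tr@triVerts))
  alphas <- sort(runif(5, -2, 30))
  prev <- alphaComplex(tr, alphas[1])
  for (al in alphas[-1]) {
    cur <- alphaComplex(tr, al)
    for (dim in names(cur))
      expect_true(all(prev[[dim]] %in% cur[[dim]]))
    prev <- cur
  }
})

test_that("filtration monotonicity holds on every build", {
  for (seed in c(1, 2, 3)) {
    s <- rand_structure(60, seed = seed)
    tr <- regularTriangulation(s)
    expect_true(AlphaPore:::.check_monotone(tr))
  }
})

test_that("degenerate inputs are rejected", {
  flat <- AlphaPore:::.synth_frame(
    cbind(matrix(runif(20), ncol = 2), 0), 1)  # coplanar
  expect_error(regularTriangulation(weightedStructure(flat)), "degenerate")
})
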