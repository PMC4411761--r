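test_that("radius profile spans [0, d], stays positive, and bottoms at bn", {
  tb <- tube_fixture()
  for (ch in c(tb$tm, importantPores(tb$net, tb$eps))) {
    rp <- radiusProfile(ch)
    expect_equal(rp@t[1], 0)
    expect_equal(rp@t[length(rp@t)], ch@length, tolerance = 1e-9)
    expect_true(all(rp@values > 0))
    expect_equal(min(rp@values), ch@bottleneckRadius, tolerance = 1e-12)
  }
})

test_that("the tube radius profile dips at the constriction", {
  tb <- tube_fixture()
  ch <- tb$tm[[1]]
  rp <- radiusProfile(ch)
  z <- ch@centerline[, 3]
  atNeck <- abs(z - 20) < 3
  away <- z > 5 & z < 35 & !atNeck
  expect_lt(min(rp@values[atNeck]), min(rp@values[away]))
  # the probe-calibrated constriction: clearance at the neck within 0.3 A
  cp <- clearanceProfile(ch)
  expect_equal(min(cp@values[atNeck]), 2, tolerance = 0.45)
  # clearance never exceeds the orthosphere radius
  expect_true(all(cp@values <= rp@values + 1e-9))
})

test_that("physico-chemical profiles average the lining residues", {
  tb <- tube_fixture()
  ch <- tb$tm[[1]]
  # synthetic channel with known residues
  a <- data.frame(serial = 1:8, element = "C", name = "CA",
                  resname = c("ILE", "ILE", "ILE", "ILE",
                              "ARG", "ARG", "ILE", "ILE"),
                  resno = 1:8, chain = "A",
                  x = 0, y = 0, z = 1:8, radius = 1.7, weight = 1.7^2,
                  stringsAsFactors = FALSE)
  mk <- function(tets) {
    n <- nrow(tets)
    pts <- cbind(seq(0, 10, length.out = 2 * n - 1), 0, 0)
    new("Channel", nodePath = seq_len(n), triPath = seq_len(n - 1),
        centerline = pts, arc = seq(0, 10, length.out = 2 * n - 1),
        radii = rep(1, 2 * n - 1), tetAtoms = tets,
        triAtoms = matrix(1L, n - 1, 3), length = 10,
        bottleneckRadius = 1, straightness = NA_real_, score = NA_real_,
        kind = "pore", structure = a)
  }
  kd <- scaleTable("hydropathy")
  # all-Ile node scores 4.5; two Arg + two Ile average to 0
  ch2 <- mk(rbind(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L)))
  pr <- physchemProfile(ch2, kd)
  expect_equal(pr@values, c(4.5, (4.5 + 4.5 - 4.5 - 4.5) / 2))
  expect_equal(pr@t, c(0, 10))
  # a constant scale gives a constant profile
  const <- new("ScaleTable", name = "const",
               values = stats::setNames(rep(2.5, 20), names(kd@values)))
  expect_equal(unique(physchemProfile(ch2, const)@values), 2.5)
  # non-standard residues are excluded; an all-unknown node is NA
  a2 <- a; a2$resname <- c("ILE", "ILE", "XXX", "XXX",
                           "XXX", "XXX", "XXX", "XXX")
  ch3 <- mk(rbind(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L)))
  ch3@structure <- a2
  pr3 <- physchemProfile(ch3, kd)
  expect_equal(pr3@values[1], 4.5)
  expect_true(is.na(pr3@values[2]))
  # the real channel yields finite values everywhere (tube is one residue)
  expect_true(all(is.finite(physchemProfile(ch, kd)@values) |
                    is.na(physchemProfile(ch, kd)@values)))
})

test_that("shipped scale tables cover the 20 residues with known entries", {
  kd <- scaleTable("hydropathy")
  expect_equal(unname(kd@values["ILE"]), 4.5)
  expect_equal(unname(kd@values["ARG"]), -4.5)
  ch <- scaleTable("charge")
  expect_equal(unname(ch@values[c("ASP", "GLU", "LYS", "ARG", "HIS",
                                  "ALA")]), c(-1, -1, 1, 1, 0.5, 0))
  bk <- scaleTable("bulkiness")
  expect_equal(unname(bk@values["GLY"]), 3.40)
  expect_length(bk@values, 20L)
})

test_that("conservation profiles average per-tetrahedron residue scores", {
  a <- data.frame(serial = 1:4, element = "C", name = "CA",
                  resname = "ALA", resno = 1:4, chain = "A",
                  x = 0, y = 0, z = 1:4, radius = 1.7, weight = 1.7^2,
                  stringsAsFactors = FALSE)
  pts <- cbind(c(0, 5, 10), 0, 0)
  ch <- new("Channel", nodePath = 1:2, triPath = 1L, centerline = pts,
            arc = c(0, 5, 10), radii = rep(1, 3),
            tetAtoms = rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L)),
            triAtoms = matrix(1L, 1, 3), length = 10, bottleneckRadius = 1,
            straightness = NA_real_, score = NA_real_, kind = "pore",
            structure = a)
  f <- tempfile()
  writeLines(c("A 1 1", "A 2 1", "A 3 5", "A 4 9"), f)
  tab <- readConservation(f)
  pr <- conservationProfile(ch, tab)
  expect_equal(pr@values, c(4, 4))
  # constant scores give a constant profile
  writeLines(c("A 1 9", "A 2 9", "A 3 9", "A 4 9"), f)
  expect_equal(conservationProfile(ch, readConservation(f))@values, c(9, 9))
  # missing residues drop out of the mean
  writeLines(c("A 1 2", "A 2 4"), f)
  expect_equal(conservationProfile(ch, readConservation(f))@values, c(3, 3))
  # recomputation oracle on the tube with random scores
  tb <- tube_fixture()
  chT <- tb$tm[[1]]
  at <- chT@structure
  set.seed(17)
  sc <- stats::setNames(round(runif(nrow(at), 1, 9), 2),
                        paste0(at$chain, ":", at$resno))
  tabT <- new("ConservationTable", scores = sc)
  prT <- conservationProfile(chT, tabT)
  manual <- apply(chT@tetAtoms, 1, function(v)
    mean(sc[paste0(at$chain[v], ":", at$resno[v])]))
  expect_equal(prT@values, unname(manual))
})

test_that("trilinear interpolation is exact for trilinear fields", {
  # grid sampling a linear field is reproduced exactly anywhere inside
  dims <- c(6L, 5L, 7L)
  org <- c(-1, 2, 0.5); sp <- c(0.8, 1.1, 0.6)
  lin <- function(p) 2 * p[, 1] - p[, 2] + 3 * p[, 3]
  gp <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                              y = seq_len(dims[2]) - 1,
                              z = seq_len(dims[3]) - 1))
  pts <- sweep(sweep(gp, 2, sp, "*"), 2, org, "+")
  vals <- array(NA_real_, dims)
  vals[gp + 1] <- lin(pts)
  grid <- new("ScalarGrid", origin = org, spacing = sp, dims = dims,
              values = vals)
  set.seed(23)
  q <- cbind(runif(50, org[1], org[1] + sp[1] * (dims[1] - 1)),
             runif(50, org[2], org[2] + sp[2] * (dims[2] - 1)),
             runif(50, org[3], org[3] + sp[3] * (dims[3] - 1)))
  expect_equal(interpolateGrid(grid, q), lin(q), tolerance = 1e-10)
  # grid nodes return their stored values
  expect_equal(interpolateGrid(grid, pts[c(1, 17, 100), , drop = FALSE]),
               lin(pts[c(1, 17, 100), , drop = FALSE]), tolerance = 1e-12)
  # out-of-bounds points are refused by name
  expect_error(interpolateGrid(grid, rbind(org - 5)), "outside")

  # full trilinear polynomial inside one cell
  tri8 <- function(p) 1 + 2 * p[, 1] - p[, 2] + 0.5 * p[, 3] +
    0.3 * p[, 1] * p[, 2] - 0.7 * p[, 2] * p[, 3] + 0.2 * p[, 3] * p[, 1] +
    0.11 * p[, 1] * p[, 2] * p[, 3]
  vals2 <- array(NA_real_, dims)
  vals2[gp + 1] <- tri8(pts)
  grid2 <- new("ScalarGrid", origin = org, spacing = sp, dims = dims,
               values = vals2)
  cell <- cbind(runif(30, org[1], org[1] + sp[1]),
                runif(30, org[2], org[2] + sp[2]),
                runif(30, org[3], org[3] + sp[3]))
  expect_equal(interpolateGrid(grid2, cell), tri8(cell), tolerance = 1e-10)
})

test_that("OpenDX grids parse and feed electrostatic profiles", {
  dx <- tempfile(fileext = ".dx")
  nx <- 4L; ny <- 3L; nz <- 5L
  vals <- numeric(nx * ny * nz)
  idx <- 0
  for (i in 0:(nx - 1)) for (j in 0:(ny - 1)) for (k in 0:(nz - 1)) {
    idx <- idx + 1
    vals[idx] <- i - 2 * j + 0.5 * k   # z fastest, APBS order
  }
  lines <- c("# Comment", sprintf(
    "object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    "origin 0.0 0.0 0.0",
    "delta 1.0 0.0 0.0", "delta 0.0 1.0 0.0", "delta 0.0 0.0 1.0",
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            nx * ny * nz),
    apply(matrix(c(vals, NA, NA)[1:(ceiling(length(vals) / 3) * 3)],
                 ncol = 3, byrow = TRUE), 1,
          function(r) paste(r[!is.na(r)], collapse = " ")),
    'attribute "dep" string "positions"')
  writeLines(lines, dx)
  g <- readOpenDX(dx)
  expect_equal(g@dims, c(nx, ny, nz))
  # value at grid index (i, j, k) must match the generating field
  expect_equal(g@values[2, 1, 3], 1 - 0 + 0.5 * 2)
  expect_equal(interpolateGrid(g, rbind(c(1.5, 1.5, 1.5))),
               1.5 - 3 + 0.75, tolerance = 1e-10)

  # electrostatic profile = interpolation along the centerline
  a <- AlphaPore:::.empty_atoms()
  pts <- cbind(seq(0.2, 2.8, length.out = 5), 1, 2)
  ch <- new("Channel", nodePath = 1:3, triPath = 1:2, centerline = pts,
            arc = seq(0, 2.6, length.out = 5), radii = rep(1, 5),
            tetAtoms = matrix(1L, 3, 4), triAtoms = matrix(1L, 2, 3),
            length = 2.6, bottleneckRadius = 1, straightness = NA_real_,
            score = NA_real_, kind = "pore", structure = a)
  ep <- electrostaticProfile(ch, g)
  expect_equal(ep@values, pts[, 1] - 2 * pts[, 2] + 0.5 * pts[, 3],
               tolerance = 1e-10)
})

test_that("Monte-Carlo channel volume matches its limits and a voxel oracle", {
  # two far-apart small atoms: tets uncovered, volume = sum of tet volumes
  a <- data.frame(serial = 1:5, element = "C", name = "C", resname = "UNK",
                  resno = 1:5, chain = "A",
                  x = c(0, 4, 0, 0, 4), y = c(0, 0, 4, 0, 4),
                  z = c(0, 0, 0, 4, 4),
                  radius = 0.01, weight = 1e-4, stringsAsFactors = FALSE)
  tets <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  mkch <- function(atoms) {
    pts <- cbind(c(0, 1, 2), 0, 0)
    new("Channel", nodePath = 1:2, triPath = 1L, centerline = pts,
        arc = c(0, 1, 2), radii = rep(1, 3), tetAtoms = tets,
        triAtoms = matrix(2:4, 1), length = 2, bottleneckRadius = 1,
        straightness = NA_real_, score = NA_real_, kind = "pore",
        structure = atoms)
  }
  ch <- mkch(a)
  P <- as.matrix(a[, c("x", "y", "z")])
  exact <- sum(AlphaPore:::.tet_volumes(P, tets))
  v <- channelVolume(ch, mcSamples = 40000, seed = 2)
  expect_equal(v$volume, exact, tolerance = 3 * max(v$stderr, 1e-6) / exact)
  # determinism
  v2 <- channelVolume(ch, mcSamples = 40000, seed = 2)
  expect_identical(v$volume, v2$volume)
  expect_error(channelVolume(ch, mcSamples = 10), "1000")

  # one huge ball covering everything: volume ~ 0
  a3 <- a; a3$radius <- 10; a3$weight <- 100
  v3 <- channelVolume(mkch(a3), mcSamples = 5000, seed = 3)
  expect_equal(v3$volume, 0, tolerance = 1e-9)

  # partial coverage vs a dense voxel oracle
  a4 <- a; a4$radius <- 1.3; a4$weight <- 1.3^2
  v4 <- channelVolume(mkch(a4), mcSamples = 200000, seed = 4)
  h <- 0.08
  gx <- seq(-0.5, 4.5, by = h)
  gp <- as.matrix(expand.grid(gx, gx, gx))
  inTet <- function(p, v) {
    M <- cbind(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ],
               P[v[4], ] - P[v[1], ])
    b <- solve(M, t(sweep(p, 2, P[v[1], ])))
    b[1, ] >= 0 & b[2, ] >= 0 & b[3, ] >= 0 & colSums(b) <= 1
  }
  inside <- inTet(gp, tets[1, ]) | inTet(gp, tets[2, ])
  cov <- rep(FALSE, nrow(gp))
  for (j in 1:5) {
    cov <- cov | (gp[, 1] - P[j, 1])^2 + (gp[, 2] - P[j, 2])^2 +
      (gp[, 3] - P[j, 3])^2 <= 1.3^2
  }
  oracle <- sum(inside & !cov) * h^3
  expect_equal(v4$volume, oracle, tolerance = 0.02 * oracle)
})

test_that("profiles are invariant under rigid motion of the whole scene", {
  tb <- tube_fixture()
  ch <- tb$tm[[1]]
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  a2 <- ch@structure
  xyz <- as.matrix(a2[, c("x", "y", "z")]) %*% t(R)
  a2$x <- xyz[, 1] + shift[1]; a2$y <- xyz[, 2] + shift[2]
  a2$z <- xyz[, 3] + shift[3]
  ch2 <- ch
  ch2@structure <- a2
  ch2@centerline <- sweep(ch@centerline %*% t(R), 2, shift, "+")
  expect_equal(clearanceProfile(ch2)@values, clearanceProfile(ch)@values,
               tolerance = 1e-8)
  expect_equal(physchemProfile(ch2, scaleTable("hydropathy"))@values,
               physchemProfile(ch, scaleTable("hydropathy"))@values)
})

test_that("profile CSV export writes (t, value) rows", {
  p <- new("ChannelProfile", name = "radius", t = c(0, 1, 2),
           values = c(3, 2.5, 3.1), d = 2)
  f <- tempfile(fileext = ".csv")
  writeProfileCSV(p, f)
  back <- utils::read.csv(f)
  expect_equal(back$t, p@t)
  expect_equal(back$value, p@values)
})
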