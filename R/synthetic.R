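# Synthetic ball arrangements with known geometry, so every pipeline stage
# can be validated without downloading structures.  All generators are
# deterministic given their seed and write ordinary WeightedStructure
# objects, so they can be exported as PDB for external cross-checks.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.synth_frame <- function(xyz, atomRadius, resname = "UNK") {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n), element = rep("C", n),
             name = rep("C", n), resname = rep(resname, n),
             resno = seq_len(n), chain = rep("A", n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             radius = rep(atomRadius, n), weight = rep(atomRadius^2, n),
             stringsAsFactors = FALSE)
}

#' Synthetic hollow tube with a calibrated constriction
#'
#' Atoms are placed on rings around the z axis forming a hollow cylinder
#' open at both ends (z = 0 and z = length).  Rings near
#' \code{constrictionPosition * length} are pinched smoothly so that the
#' largest spherical probe that can pass the constriction has radius
#' \code{constrictionRadius}: the pinched ring sits at
#' \code{constrictionRadius + atomRadius} from the axis.  The wall is two
#' atom layers thick so the only openings are the tube ends.
#'
#' @param length tube length (A).
#' @param lumenRadius unpinched lumen (probe) radius (A).
#' @param constrictionRadius probe radius at the constriction (A); must be
#'   positive and smaller than \code{lumenRadius}.
#' @param constrictionPosition fractional position of the pinch along z.
#' @param outerRadius outer radius of the wall (A).
#' @param atomRadius van der Waals radius given to every ball (A).
#' @param neckHalfWidth half-width of the smooth pinch along z (A).
#' @param jitter positional disorder (A).  Perfect lattices are unlike
#'   molecular surfaces and produce extreme sliver tetrahedra; a quarter
#'   Angstrom of disorder emulates atomic roughness.  The constriction
#'   ring keeps its exact radial distance so the calibration holds.
#' @param seed deterministic jitter seed.
#' @return a [WeightedStructure-class].
#' @export
makeTube <- function(length = 40, lumenRadius = 4, constrictionRadius = 2,
                     constrictionPosition = 0.5,
                     outerRadius = lumenRadius + 2 * atomRadius + 1.5,
                     atomRadius = 1.7, neckHalfWidth = 4, jitter = 0.25,
                     seed = 1L) {
  if (!(lumenRadius > constrictionRadius && constrictionRadius > 0))
    stop("need lumenRadius > constrictionRadius > 0", call. = FALSE)
  if (outerRadius <= lumenRadius + atomRadius)
    stop("outerRadius leaves no room for the wall", call. = FALSE)
  dz <- 1.4
  arc <- 1.4
  zc <- constrictionPosition * length
  # ring grid anchored at the constriction so one ring sits exactly at zc
  zs <- sort(unique(c(rev(seq(zc, 0, by = -dz)), seq(zc, length, by = dz))))
  lumenAt <- function(z) {
    u <- abs(z - zc) / neckHalfWidth
    base <- ifelse(u >= 1, lumenRadius,
                   constrictionRadius +
                     (lumenRadius - constrictionRadius) * 0.5 * (1 - cos(pi * u)))
    # funnel-shaped mouths: the lumen flares open over the last few
    # Angstroms, as real channel mouths do; flat end-caps would be
    # atomically planar, which no molecular surface is
    edge <- pmin(z, length - z)
    flare <- pmax(0, 1 - edge / 3.5)
    pmin(base + flare^2 * (outerRadius - atomRadius - base),
         outerRadius - 2 * atomRadius)
  }
  .with_seed(seed, {
    rows <- vector("list", 0L)
    for (i in seq_along(zs)) {
      z <- zs[i]
      rin <- lumenAt(z) + atomRadius
      radii <- seq(rin, outerRadius - atomRadius, by = 1.3)
      if (max(radii) < outerRadius - atomRadius - 0.6)
        radii <- c(radii, outerRadius - atomRadius)
      for (j in seq_along(radii)) {
        rho <- radii[j]
        nat <- max(6L, ceiling(2 * pi * rho / arc))
        phi0 <- (i * 2.399963 + j * 1.1) %% (2 * pi)
        phi <- phi0 + 2 * pi * (seq_len(nat) - 1) / nat
        ring <- cbind(rho * cos(phi), rho * sin(phi), rep(z, nat))
        ring <- ring + matrix(stats::runif(3 * nat, -jitter, jitter),
                              ncol = 3)
        isCal <- abs(z - zc) < 1e-9 && j == 1L
        if (isCal) {
          # restore the exact radial distance of the calibration ring
          rr <- sqrt(ring[, 1]^2 + ring[, 2]^2)
          ring[, 1] <- ring[, 1] * rho / rr
          ring[, 2] <- ring[, 2] * rho / rr
        }
        rows[[base::length(rows) + 1L]] <- ring
      }
    }
    xyz <- do.call(rbind, rows)
    # jagged rims: the cut height varies with the azimuth and per atom,
    # so mouth rims are rough at the ~1.5 A scale like protein mouths
    phi <- atan2(xyz[, 2], xyz[, 1])
    jagTop <- 1.0 * (1 + sin(3 * phi + 0.7)) / 2 +
      stats::runif(nrow(xyz), 0, 0.8)
    jagBot <- 1.0 * (1 + sin(2 * phi + 2.1)) / 2 +
      stats::runif(nrow(xyz), 0, 0.8)
    keep <- xyz[, 3] < length - jagTop & xyz[, 3] > jagBot
    # never cut the calibrated neck
    keep <- keep | abs(xyz[, 3] - zc) < neckHalfWidth
    xyz <- xyz[keep, , drop = FALSE]
    weightedStructure(.synth_frame(xyz, atomRadius, "TUB"),
                      id = sprintf("tube_L%g_lum%g_con%g", length,
                                   lumenRadius, constrictionRadius))
  })
}

#' Synthetic solid blob
#'
#' A dense cubic-lattice ball cluster trimmed to a sphere: no mouths, no
#' channels; its alpha complex at 0 covers the whole hull.
#'
#' @param radius blob radius (A).
#' @param spacing lattice spacing (A); must be small enough that
#'   neighbouring balls overlap.
#' @param atomRadius ball radius (A).
#' @param jitter positional disorder (A), see [makeTube()].
#' @param seed jitter seed.
#' @return a [WeightedStructure-class].
#' @export
makeBlob <- function(radius = 7, spacing = 1.4, atomRadius = 1.7,
                     jitter = 0.25, seed = 1L) {
  g <- seq(-radius, radius, by = spacing)
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  xyz <- xyz[sqrt(rowSums(xyz^2)) <= radius, , drop = FALSE]
  .with_seed(seed, {
    xyz <- xyz + matrix(stats::runif(3 * nrow(xyz), -jitter, jitter), ncol = 3)
    weightedStructure(.synth_frame(xyz, atomRadius, "BLB"),
                      id = sprintf("blob_r%g", radius))
  })
}

#' Synthetic hollow shell with a sealed interior cavity
#'
#' Two concentric Fibonacci-sphere layers of overlapping balls; the interior
#' is an inaccessible void that must be pruned from the channel network.
#'
#' @param innerRadius cavity radius (A).
#' @param atomRadius ball radius (A).
#' @param jitter positional disorder (A), see [makeTube()].
#' @param seed jitter seed.
#' @return a [WeightedStructure-class].
#' @export
makeShell <- function(innerRadius = 6, atomRadius = 1.7, jitter = 0.2,
                      seed = 1L) {
  fib <- function(r, spacing) {
    n <- max(16L, ceiling(4 * pi * r^2 / spacing^2))
    i <- seq_len(n) - 0.5
    th <- acos(1 - 2 * i / n)
    ph <- pi * (1 + sqrt(5)) * i
    cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  }
  r1 <- innerRadius + atomRadius
  xyz <- rbind(fib(r1, 1.25), fib(r1 + 1.2, 1.25))
  .with_seed(seed, {
    xyz <- xyz + matrix(stats::runif(3 * nrow(xyz), -jitter, jitter), ncol = 3)
    weightedStructure(.synth_frame(xyz, atomRadius, "SHL"),
                      id = sprintf("shell_r%g", innerRadius))
  })
}

#' Synthetic multi-pore barrel
#'
#' A rectangular lattice slab with \code{nPores} parallel cylindrical holes
#' drilled along z, each of probe radius \code{poreRadius}.
#'
#' @param nPores number of holes.
#' @param poreRadius probe radius of each hole (A).
#' @param height slab height (A).
#' @param spacing lattice spacing (A).
#' @param atomRadius ball radius (A).
#' @param jitter positional disorder (A), see [makeTube()].
#' @param seed jitter seed.
#' @return a [WeightedStructure-class].
#' @export
makeBarrel <- function(nPores = 2, poreRadius = 3, height = 20,
                       spacing = 1.4, atomRadius = 1.7, jitter = 0.25,
                       seed = 1L) {
  pitch <- 2 * (poreRadius + atomRadius) + 4
  cx <- (seq_len(nPores) - (nPores + 1) / 2) * pitch
  gx <- seq(min(cx) - poreRadius - 4, max(cx) + poreRadius + 4, by = spacing)
  gy <- seq(-poreRadius - 4, poreRadius + 4, by = spacing)
  gz <- seq(0, height, by = spacing)
  xyz <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keep <- rep(TRUE, nrow(xyz))
  for (c0 in cx) {
    d <- sqrt((xyz[, 1] - c0)^2 + xyz[, 2]^2)
    keep <- keep & d > poreRadius + atomRadius
  }
  xyz <- xyz[keep, , drop = FALSE]
  .with_seed(seed, {
    xyz <- xyz + matrix(stats::runif(3 * nrow(xyz), -jitter, jitter), ncol = 3)
    weightedStructure(.synth_frame(xyz, atomRadius, "BRL"),
                      id = sprintf("barrel_%dpores", nPores))
  })
}
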