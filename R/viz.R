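# 2D channel visualization: node-box/atom-box diagrams, the radius-profile
# projection view, and PyMOL / union-of-balls exports.

.diverging_map <- function(v) {
  # blue (low) -> white -> red (high)
  if (all(is.na(v))) return(rep("#F7F7F7", length(v)))
  rng <- range(v, na.rm = TRUE)
  u <- if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  u[is.na(u)] <- 0.5
  grDevices::rgb(grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))(u),
                 maxColorValue = 255)
}

.color_keys <- c("element", "polarity", "hydropathy", "conservation",
                 "bulkiness", "charge")

.polar_res <- c("ARG", "LYS", "HIS", "ASP", "GLU", "ASN", "GLN", "SER",
                "THR", "TYR", "CYS", "TRP")

.atom_color_value <- function(atoms, idx, colorBy, conservation = NULL) {
  switch(colorBy,
    element = as.numeric(factor(atoms$element[idx],
                                levels = sort(unique(atoms$element)))),
    polarity = as.numeric(atoms$resname[idx] %in% .polar_res),
    hydropathy = unname(scaleTable("hydropathy")@values[atoms$resname[idx]]),
    bulkiness = unname(scaleTable("bulkiness")@values[atoms$resname[idx]]),
    charge = unname(scaleTable("charge")@values[atoms$resname[idx]]),
    conservation = {
      if (is.null(conservation))
        stop("conservation coloring needs a ConservationTable",
             call. = FALSE)
      conservationScore(conservation, atoms$chain[idx], atoms$resno[idx])
    },
    stop("unknown color_by '", colorBy, "'; valid keys: ",
         paste(.color_keys, collapse = ", "), call. = FALSE))
}

#' 2D node-box / atom-box diagram of a channel
#'
#' Each path tetrahedron becomes a node box of four atom-box slots;
#' adjacent boxes are connected by the three atoms of their shared
#' triangle.  Slot assignment is stable: atoms shared with the previous
#' box keep their slot, so runs of consecutive identical atoms can be
#' merged into one visual box (reported in \code{merges}).
#'
#' @param ch a [Channel-class].
#' @param colorBy one of \code{element}, \code{polarity},
#'   \code{hydropathy}, \code{bulkiness}, \code{charge},
#'   \code{conservation}.
#' @param conservation a [ConservationTable-class] when
#'   \code{colorBy = "conservation"}.
#' @return a [BoxDiagram-class].
#' @export
boxDiagram <- function(ch, colorBy = "element", conservation = NULL) {
  if (!colorBy %in% .color_keys)
    stop("unknown color_by '", colorBy, "'; valid keys: ",
         paste(.color_keys, collapse = ", "), call. = FALSE)
  a <- ch@structure
  tets <- ch@tetAtoms
  n <- nrow(tets)
  slots <- matrix(NA_integer_, n, 4)
  slots[1, ] <- sort(tets[1, ])
  if (n > 1) {
    for (i in 2:n) {
      prev <- slots[i - 1, ]
      cur <- tets[i, ]
      out <- rep(NA_integer_, 4)
      stay <- intersect(prev, cur)
      out[match(stay, prev)] <- stay
      newcomers <- setdiff(cur, stay)
      out[is.na(out)] <- newcomers
      slots[i, ] <- out
    }
  }
  connectors <- lapply(seq_len(max(0, n - 1)), function(i)
    unname(sort(ch@triAtoms[i, ])))
  labels <- matrix(sprintf("%s%d:%s", a$resname[slots], a$resno[slots],
                           a$name[slots]), n, 4)
  cv <- matrix(.atom_color_value(a, as.vector(slots), colorBy, conservation),
               n, 4)
  merges <- do.call(rbind, lapply(1:4, function(s) {
    r <- rle(slots[, s])
    ends <- cumsum(r$lengths)
    data.frame(slot = s, start = ends - r$lengths + 1L, end = ends,
               atom = r$values)
  }))
  merges <- merges[order(merges$start, merges$slot), , drop = FALSE]
  rownames(merges) <- NULL
  new("BoxDiagram", slots = slots, labels = labels, colorValues = cv,
      colorBy = colorBy, connectors = connectors, merges = merges)
}

#' Write a box diagram as JSON
#' @param bd a [BoxDiagram-class].
#' @param path output file.
#' @export
writeDiagramJSON <- function(bd, path) {
  jsonlite::write_json(
    list(color_by = bd@colorBy, slots = bd@slots, labels = bd@labels,
         color_values = bd@colorValues, connectors = bd@connectors,
         merges = bd@merges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a box diagram as SVG
#'
#' Merged atom boxes are drawn as single rectangles spanning their run;
#' connectors join adjacent node boxes; tetrahedron indices (path-local)
#' are printed under the node boxes.
#'
#' @param bd a [BoxDiagram-class].
#' @param path output .svg file.
#' @param boxW,boxH box width/height in px.
#' @export
writeDiagramSVG <- function(bd, path, boxW = 46, boxH = 26) {
  n <- nrow(bd@slots)
  gap <- 22
  W <- n * boxW + (n - 1) * gap + 40
  H <- 4 * boxH + 70
  col <- matrix(.diverging_map(as.vector(bd@colorValues)), n, 4)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d">'), W, H),
           '<rect width="100%" height="100%" fill="white"/>')
  xs <- 20 + (seq_len(n) - 1) * (boxW + gap)
  # connectors behind the boxes
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (atom in bd@connectors[[i]]) {
        s1 <- match(atom, bd@slots[i, ])
        s2 <- match(atom, bd@slots[i + 1, ])
        y1 <- 20 + (s1 - 0.5) * boxH
        y2 <- 20 + (s2 - 0.5) * boxH
        out <- c(out, sprintf(
          '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="#555"/>',
          xs[i] + boxW, y1, xs[i + 1], y2))
      }
    }
  }
  for (r in seq_len(nrow(bd@merges))) {
    m <- bd@merges[r, ]
    i1 <- m$start; i2 <- m$end; s <- m$slot
    x <- xs[i1]
    wdt <- xs[i2] + boxW - x
    y <- 20 + (s - 1) * boxH
    out <- c(out, sprintf(
      paste0('<rect x="%g" y="%g" width="%g" height="%g" fill="%s" ',
             'stroke="black"/>'), x, y, wdt, boxH, col[i1, s]),
      sprintf(paste0('<text x="%g" y="%g" font-size="8" ',
                     'text-anchor="middle">%s</text>'),
              x + wdt / 2, y + boxH / 2 + 3, bd@labels[i1, s]))
  }
  out <- c(out, sprintf(
    paste0('<text x="%g" y="%g" font-size="10" ',
           'text-anchor="middle">%d</text>'),
    xs + boxW / 2, 20 + 4 * boxH + 16, seq_len(n)), '</svg>')
  writeLines(out, path)
  invisible(path)
}

#' Plot-ready projection view of a channel
#'
#' The channel is projected to 2D as the symmetric region bounded by
#' +/- radius(t); an overlay profile (resampled onto the radius grid)
#' drives a blue-to-red diverging colour map.  With a second overlay the
#' region is split: upper half coloured by the first, lower by the second.
#'
#' @param radius the radius [ChannelProfile-class].
#' @param overlay profile colour-mapped over the region.
#' @param secondOverlay optional second profile for the split view.
#' @return data.frame with columns \code{t}, \code{upper}, \code{lower},
#'   \code{upperValue}, \code{upperColor} and (split view)
#'   \code{lowerValue}, \code{lowerColor}.
#' @export
projectionView <- function(radius, overlay, secondOverlay = NULL) {
  if (length(radius@t) == 0 || length(overlay@t) == 0)
    stop("empty profile", call. = FALSE)
  res <- function(p) stats::approx(p@t, p@values, xout = radius@t,
                                   rule = 2)$y
  ov <- res(overlay)
  df <- data.frame(t = radius@t, upper = radius@values,
                   lower = -radius@values,
                   upperValue = ov, upperColor = .diverging_map(ov))
  if (!is.null(secondOverlay)) {
    ov2 <- res(secondOverlay)
    df$lowerValue <- ov2
    df$lowerColor <- .diverging_map(ov2)
  } else {
    df$lowerValue <- ov
    df$lowerColor <- df$upperColor
  }
  df
}

#' Export a channel as a PyMOL script
#'
#' Draws the union-of-balls representation (one sphere per centerline
#' sample, radius from the radius profile) as pseudoatoms, plus a named
#' selection of the residues lining the channel.  Output is deterministic:
#' the same channel always yields a byte-identical script.
#'
#' @param ch a [Channel-class].
#' @param path output .pml file.
#' @param name object name used inside PyMOL.
#' @return invisibly, the path.
#' @export
exportPyMOL <- function(ch, path, name = "channel") {
  pts <- ch@centerline
  r <- ch@radii
  lines <- c("# channel union-of-balls export",
             "from pymol import cmd")
  for (i in seq_len(nrow(pts))) {
    lines <- c(lines, sprintf(
      paste0("cmd.pseudoatom('%s', pos=[%.4f, %.4f, %.4f], ",
             "vdw=%.4f, name='S%d')"),
      name, pts[i, 1], pts[i, 2], pts[i, 3], r[i], i))
  }
  a <- ch@structure
  idx <- sort(unique(as.vector(ch@tetAtoms)))
  res <- unique(data.frame(chain = a$chain[idx], resno = a$resno[idx]))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  sel <- paste(sprintf("(chain %s and resi %d)", res$chain, res$resno),
               collapse = " or ")
  lines <- c(lines,
             sprintf("cmd.select('%s_lining', '%s')", name, sel),
             sprintf("cmd.show('spheres', '%s')", name),
             sprintf("cmd.set('sphere_transparency', 0.3, '%s')", name))
  writeLines(lines, path)
  invisible(path)
}
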