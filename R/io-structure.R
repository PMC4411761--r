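# Van der Waals radii (Bondi-style). The radius table materially shifts
# bottleneck radii, so it is exposed and overridable everywhere a structure
# is built.

.vdw_default <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_fallback <- 1.70

#' Van der Waals radius lookup
#'
#' Total lookup: every element symbol maps to a positive radius; symbols not
#' in the table get the carbon-like default of 1.70 A.
#'
#' @param element character vector of element symbols.
#' @param table named numeric vector of radii (A) overriding the default
#'   Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80).
#' @return numeric vector of radii (A).
#' @export
vdwRadius <- function(element, table = .vdw_default) {
  r <- unname(table[toupper(element)])
  r[is.na(r)] <- .vdw_fallback
  r
}

.water_res <- c("HOH", "WAT", "DOD", "H2O")

# element symbol from a PDB atom name when the element column is blank
.element_from_name <- function(name) {
  nm <- gsub("[0-9' ]", "", toupper(name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
         two, substr(nm, 1, 1))
}

.atom_frame <- function(serial, element, name, resname, resno, chain,
                        x, y, z, radiusTable = .vdw_default) {
  radius <- vdwRadius(element, radiusTable)
  data.frame(serial = as.integer(serial), element = as.character(element),
             name = as.character(name), resname = as.character(resname),
             resno = as.integer(resno), chain = as.character(chain),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             radius = radius, weight = radius^2,
             stringsAsFactors = FALSE)
}

.empty_atoms <- function() .atom_frame(integer(), character(), character(),
                                       character(), integer(), character(),
                                       numeric(), numeric(), numeric())

#' Build a weighted structure from an atom table
#'
#' Exact duplicate centres are dropped (later occurrence loses) with a
#' warning, since the regular triangulation requires distinct sites.
#'
#' @param atoms data.frame as produced internally (see
#'   [WeightedStructure-class]).
#' @param id label.
#' @param het optional HETATM table kept aside for active-site seeding.
#' @return a [WeightedStructure-class].
#' @export
weightedStructure <- function(atoms, id = "structure", het = .empty_atoms()) {
  if (nrow(atoms) > 0) {
    key <- paste(atoms$x, atoms$y, atoms$z)
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " atom(s) with duplicate centers dropped")
      atoms <- atoms[!dup, , drop = FALSE]
    }
    rownames(atoms) <- NULL
  }
  new("WeightedStructure", atoms = atoms, het = het, id = id)
}

#' Read a PDB file into a weighted structure
#'
#' Parses ATOM (and optionally HETATM) records via \pkg{bio3d}, keeps only
#' blank or 'A' alternate locations, excludes waters and (by default)
#' hydrogens, and assigns van der Waals radii by element lookup.  HETATM
#' atoms are never part of the ball model; when \code{keepHetatm} they are
#' retained in a side table for active-site seeding.
#'
#' @param path PDB file.
#' @param keepHetatm retain HETATM records in the side table (default TRUE).
#' @param keepHydrogens include hydrogens in the ball model (default FALSE).
#' @param radiusTable see [vdwRadius()].
#' @param id label (defaults to the file name).
#' @return a [WeightedStructure-class].
#' @export
readStructure <- function(path, keepHetatm = TRUE, keepHydrogens = FALSE,
                          radiusTable = .vdw_default, id = basename(path)) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- .element_from_name(a$elety[bad])
  elem <- trimws(toupper(elem))
  alt <- trimws(a$alt)
  keepAlt <- is.na(alt) | alt == "" | alt == "A"
  water <- toupper(a$resid) %in% .water_res
  hyd <- elem %in% c("H", "D")

  sel <- a$type == "ATOM" & keepAlt & !water
  if (!keepHydrogens) sel <- sel & !hyd
  ball <- .atom_frame(a$eleno[sel], elem[sel], trimws(a$elety[sel]),
                      trimws(a$resid[sel]), a$resno[sel], a$chain[sel],
                      a$x[sel], a$y[sel], a$z[sel], radiusTable)
  if (nrow(ball) < 4)
    stop("degenerate input: fewer than 4 usable ATOM records", call. = FALSE)

  hetsel <- a$type == "HETATM" & keepAlt & !water & keepHetatm
  het <- .atom_frame(a$eleno[hetsel], elem[hetsel], trimws(a$elety[hetsel]),
                     trimws(a$resid[hetsel]), a$resno[hetsel],
                     a$chain[hetsel], a$x[hetsel], a$y[hetsel], a$z[hetsel],
                     radiusTable)
  weightedStructure(ball, id = id, het = het)
}

#' Write a structure as PDB
#'
#' Writes the ball-model atoms so external tools can cross-check synthetic
#' structures.  Coordinates are written at the standard 3-decimal PDB
#' precision.
#'
#' @param s a [WeightedStructure-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStructurePDB <- function(s, path) {
  a <- s@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), eleno = a$serial,
                   elety = a$name, resid = a$resname, chain = a$chain,
                   resno = a$resno, elesy = a$element)
  invisible(path)
}

#' Read a per-residue conservation table
#'
#' Whitespace- or tab-separated rows of \code{chain residue_number score}.
#' Duplicate (chain, residue) rows are resolved last-wins with a warning.
#'
#' @param path TSV file.
#' @return a [ConservationTable-class].
#' @export
readConservation <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0)
    return(new("ConservationTable", scores = stats::setNames(numeric(), character())))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 3))
    stop("malformed conservation row at line ",
         which(nf != 3)[1], ": expected 'chain resno score'", call. = FALSE)
  chain <- vapply(parts, `[`, "", 1L)
  resno <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  score <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- is.na(resno) | is.na(score)
  if (any(bad))
    stop("malformed conservation row at line ", which(bad)[1], call. = FALSE)
  key <- paste0(chain, ":", resno)
  if (anyDuplicated(key)) {
    warning("duplicate conservation rows; last value wins")
    keep <- !duplicated(key, fromLast = TRUE)
    key <- key[keep]; score <- score[keep]
  }
  new("ConservationTable", scores = stats::setNames(score, key))
}

#' Write a conservation table
#' @param tab a [ConservationTable-class].
#' @param path output file.
#' @export
writeConservation <- function(tab, path) {
  key <- strsplit(names(tab@scores), ":", fixed = TRUE)
  writeLines(sprintf("%s\t%s\t%.6g",
                     vapply(key, `[`, "", 1L), vapply(key, `[`, "", 2L),
                     unname(tab@scores)), path)
  invisible(path)
}

#' Query conservation scores
#'
#' @param tab a [ConservationTable-class].
#' @param chain,resno vectors identifying residues.
#' @param missing sentinel returned for absent residues (default NA).
#' @return numeric vector of scores.
#' @export
conservationScore <- function(tab, chain, resno, missing = NA_real_) {
  v <- unname(tab@scores[paste0(chain, ":", resno)])
  v[is.na(v)] <- missing
  v
}
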