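#' @import methods
NULL

#' Weighted ball model of a molecular structure
#'
#' Holds one weighted point per atom: the centre is the atomic position and
#' the weight is the squared van der Waals radius, so that the power distance
#' \eqn{\pi_p(x) = \|x - p\|^2 - w_p} vanishes exactly on the ball surface.
#' HETATM records accepted at read time are kept in a separate table: they do
#' not enter the ball model but can seed active-site searches.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{element},
#'   \code{name}, \code{resname}, \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{weight}.
#' @slot het data.frame of retained HETATM records (same columns).
#' @slot id free-text label.
#' @export
setClass("WeightedStructure",
  representation(atoms = "data.frame", het = "data.frame", id = "character"))

setValidity("WeightedStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "element", "name", "resname", "resno", "chain",
            "x", "y", "z", "radius", "weight")
  if (!all(need %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) > 0) {
    if (any(a$radius <= 0)) return("all radii must be positive")
    if (any(abs(a$weight - a$radius^2) > 1e-12))
      return("weight must equal radius^2")
  }
  TRUE
})

#' Regular triangulation with alpha values
#'
#' The weighted Delaunay triangulation of the atom centres, with per-simplex
#' orthocentres, size values (squared orthoradii), attachment flags and alpha
#' values, i.e. the full alpha-complex filtration.  Simplices of dimension
#' 0..3 are stored in flat parallel vectors/matrices.
#'
#' @slot structure the [WeightedStructure-class] that was triangulated.
#' @slot tetVerts integer matrix (m x 4) of atom indices per tetrahedron.
#' @slot tetCenter,tetSize orthocentres (m x 3) and size values; for
#'   tetrahedra the alpha value equals the size value.
#' @slot tetApex the representative interior point of each tetrahedron:
#'   the orthocentre when it falls inside the tetrahedron, otherwise the
#'   apex of its widest facet (sliver tetrahedra have orthocentres
#'   arbitrarily far from the molecule).
#' @slot tetAperture min power distance over all atoms at the apex (A^2).
#' @slot tetTris integer matrix (m x 4): triangle ids of each tetrahedron.
#' @slot triVerts,triCenter,triSize,triAttached,triAlpha triangle data.
#' @slot triAperture clamped aperture of each triangle (A^2): the largest
#'   squared probe radius that fits through the triangle's gap -- the
#'   orthoradius squared when the orthocentre falls inside the triangle,
#'   otherwise the best clamped edge aperture.  Unlike the raw size value
#'   this is bounded by the local geometry even for sliver triangles.
#' @slot triApex the most-open crossing point of each triangle (t x 3).
#' @slot triTets integer matrix (t x 2); second column \code{NA} for hull
#'   triangles.
#' @slot triHull logical: triangle lies on the convex hull.
#' @slot edgeVerts,edgeCenter,edgeSize,edgeAttached,edgeAlpha edge data.
#' @slot vertAlpha,vertAttached per-vertex alpha data (indexed by atom).
#' @slot hidden integer indices of redundant atoms absent from all simplices.
#' @slot joggleSeed seed of the deterministic joggle that resolved ties.
#' @export
setClass("RegularTriangulation",
  representation(structure = "WeightedStructure",
                 tetVerts = "matrix", tetCenter = "matrix", tetSize = "numeric",
                 tetApex = "matrix", tetAperture = "numeric",
                 tetTris = "matrix",
                 triVerts = "matrix", triCenter = "matrix", triSize = "numeric",
                 triAttached = "logical", triAlpha = "numeric",
                 triAperture = "numeric", triApex = "matrix",
                 triTets = "matrix", triHull = "logical",
                 edgeVerts = "matrix", edgeCenter = "matrix",
                 edgeSize = "numeric", edgeAttached = "logical",
                 edgeAlpha = "numeric",
                 vertAlpha = "numeric", vertAttached = "logical",
                 hidden = "integer", joggleSeed = "integer"))

setValidity("RegularTriangulation", function(object) {
  t2 <- object@triTets
  if (nrow(t2) > 0) {
    inc <- rowSums(!is.na(t2))
    if (any(inc[object@triHull] != 1))
      return("hull triangles must have exactly one incident tetrahedron")
    if (any(inc[!object@triHull] != 2))
      return("interior triangles must have exactly two incident tetrahedra")
  }
  TRUE
})

#' Channel network: dual graph of the alpha-complex complement
#'
#' One node per complement tetrahedron (positioned at its orthocentre), one
#' edge per complement triangle.  Hull triangles in the complement are mouth
#' triangles; their incident tetrahedra are boundary nodes, linked to a
#' single distinguished EXTERIOR node (id 0).
#'
#' @slot triangulation the underlying [RegularTriangulation-class].
#' @slot alpha working alpha value (default 0).
#' @slot nodes data.frame: \code{tet} (tetrahedron id, the node key),
#'   \code{x,y,z} (orthocentre), \code{width} (tet size value, A^2),
#'   \code{depth} (hops to a boundary node), \code{boundary} (flag).
#' @slot edges data.frame: \code{tri} (triangle id), \code{from,to}
#'   (tetrahedron ids; \code{to = 0} means EXTERIOR), \code{length} (A),
#'   \code{width} (triangle alpha value, A^2), \code{cost}
#'   (length / width).
#' @slot mouthTriangles integer triangle ids.
#' @slot voids list of integer vectors: pruned inaccessible components.
#' @slot pruned logical.
#' @export
setClass("ChannelNetwork",
  representation(triangulation = "RegularTriangulation", alpha = "numeric",
                 nodes = "data.frame", edges = "data.frame",
                 mouthTriangles = "integer", voids = "list",
                 pruned = "logical"))

setValidity("ChannelNetwork", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(!is.finite(e$cost)) || any(e$cost < 0))
      return("edge costs must be finite and non-negative")
  }
  TRUE
})

#' Channel endpoint selection
#'
#' @slot activeSiteNode tetrahedron id of the active-site representative
#'   (NA if not requested).
#' @slot bImp boundary representatives (tetrahedron ids), one per mouth,
#'   sorted by decreasing tetrahedron persistence and truncated to k.
#' @slot alphaMax alpha at which the mouth count attains its maximum (A^2).
#' @slot mouthComponents list of integer vectors of hull-triangle ids.
#' @slot persistence named numeric: persistence of each node in `bImp`.
#' @export
setClass("EndpointSet",
  representation(activeSiteNode = "integer", bImp = "integer",
                 alphaMax = "numeric", mouthComponents = "list",
                 persistence = "numeric"))

#' A channel: ordered path of complement tetrahedra
#'
#' @slot nodePath ordered tetrahedron ids.
#' @slot triPath ordered triangle ids (one fewer than nodes).
#' @slot centerline matrix (2n-1 x 3): alternating tetrahedron and triangle
#'   orthocentres.
#' @slot arc arc-length position of each centerline point (A).
#' @slot radii orthosphere radius at each centerline point (A),
#'   \code{sqrt(alpha value)}.
#' @slot tetAtoms integer matrix (n x 4): atoms lining each path tetrahedron.
#' @slot triAtoms integer matrix (n-1 x 3).
#' @slot length polyline arc length (A).
#' @slot bottleneckRadius min orthosphere radius over path triangles (A).
#' @slot straightness multi-scale straightness in [-1, 1] (NA until scored).
#' @slot score transmembrane score f(x) (NA until ranked).
#' @slot kind "active-site", "pore" or "transmembrane".
#' @slot structure atom table of the parent structure (for lining lookups).
#' @export
setClass("Channel",
  representation(nodePath = "integer", triPath = "integer",
                 centerline = "matrix", arc = "numeric", radii = "numeric",
                 tetAtoms = "matrix", triAtoms = "matrix",
                 length = "numeric", bottleneckRadius = "numeric",
                 straightness = "numeric", score = "numeric",
                 kind = "character", structure = "data.frame"))

setValidity("Channel", function(object) {
  n <- length(object@nodePath)
  if (length(object@triPath) != max(n - 1L, 0L))
    return("triangle path must have |nodes| - 1 entries")
  if (nrow(object@centerline) != 2L * n - 1L)
    return("centerline must have 2|nodes| - 1 points")
  if (n > 1 && object@length <= 0) return("length must be positive")
  if (n > 1 && object@bottleneckRadius <= 0)
    return("bottleneck radius must be positive")
  TRUE
})

#' Widest path tree of a channel network
#'
#' Maximum spanning tree (forest) under edge width; the path between any two
#' nodes in the tree maximises, over all network paths, the minimum edge
#' width.
#'
#' @slot edges data.frame, subset of the network's finite edges.
#' @slot nodes integer tetrahedron ids spanned by the tree.
#' @slot network the parent [ChannelNetwork-class].
#' @export
setClass("WidestPathTree",
  representation(edges = "data.frame", nodes = "integer",
                 network = "ChannelNetwork"))

#' Membrane slab: two parallel planes delimiting the bilayer
#'
#' @slot normal unit 3-vector (default z axis).
#' @slot lower,upper signed offsets along the normal (A), lower < upper.
#' @export
setClass("MembraneSlab",
  representation(normal = "numeric", lower = "numeric", upper = "numeric"))

setValidity("MembraneSlab", function(object) {
  if (length(object@normal) != 3) return("normal must be a 3-vector")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    return("normal must be a unit vector")
  if (object@lower >= object@upper) return("lower offset must be < upper")
  TRUE
})

#' A 1D profile along a channel centerline
#'
#' A real-valued function sampled on [0, d], where d is the channel length.
#'
#' @slot name label.
#' @slot t strictly increasing arc-length positions; t[1] = 0,
#'   t[length(t)] = d.
#' @slot values profile values (NA where flagged missing).
#' @slot d channel length (A).
#' @export
setClass("ChannelProfile",
  representation(name = "character", t = "numeric", values = "numeric",
                 d = "numeric"))

setValidity("ChannelProfile", function(object) {
  if (length(object@t) != length(object@values))
    return("t and values must have equal length")
  if (length(object@t) > 0) {
    if (any(diff(object@t) <= 0)) return("t must be strictly increasing")
    if (abs(object@t[1]) > 1e-9) return("profile must start at t = 0")
    if (abs(object@t[length(object@t)] - object@d) > 1e-6)
      return("profile must end at t = d")
  }
  TRUE
})

#' Per-residue scalar scale table (hydropathy, charge, bulkiness, ...)
#'
#' @slot name label.
#' @slot values named numeric, names are 3-letter residue codes.
#' @export
setClass("ScaleTable",
  representation(name = "character", values = "numeric"))

setValidity("ScaleTable", function(object) {
  std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  if (!all(std %in% names(object@values)))
    return("scale must cover the 20 standard residues")
  TRUE
})

#' Per-residue conservation score table
#'
#' @slot scores named numeric; names are "chain:resno" keys.
#' @export
setClass("ConservationTable", representation(scores = "numeric"))

#' Scalar grid (e.g. an APBS electrostatic potential map)
#'
#' @slot origin 3-vector (A).
#' @slot spacing 3 positive reals (A).
#' @slot dims 3 positive integers.
#' @slot values array of dim \code{dims}.
#' @export
setClass("ScalarGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 values = "array"))

setValidity("ScalarGrid", function(object) {
  if (any(object@spacing <= 0)) return("grid spacing must be positive")
  if (length(object@values) != prod(object@dims))
    return("value count must equal the product of dims")
  TRUE
})

#' 2D node-box / atom-box channel diagram
#'
#' One node box per path tetrahedron, each holding four atom-box slots;
#' consecutive identical atoms are merged; adjacent node boxes are joined by
#' three connectors naming the shared triangle's atoms.
#'
#' @slot slots integer matrix (n x 4): atom index per slot, stable across
#'   adjacent boxes where possible.
#' @slot labels character matrix (n x 4).
#' @slot colorValues numeric matrix (n x 4): value driving the colour map.
#' @slot colorBy label of the colouring scheme.
#' @slot connectors list of n-1 integer triples (shared-triangle atoms).
#' @slot merges data.frame: \code{slot}, \code{start}, \code{end}, \code{atom}
#'   for runs of consecutive identical atoms collapsed into one visual box.
#' @export
setClass("BoxDiagram",
  representation(slots = "matrix", labels = "matrix", colorValues = "matrix",
                 colorBy = "character", connectors = "list",
                 merges = "data.frame"))
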