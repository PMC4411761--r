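---
title: "Channel and pore extraction from the alpha complex: models and design"
author: "AlphaPore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel and pore extraction from the alpha complex: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AlphaPore)
```

## The model

A molecule is represented as a union of balls: each atom is a ball of its
van der Waals radius, encoded as a weighted point with weight $w_p = r_p^2$.
The **power distance** from a weighted point $p$ to a query point $x$ is

$$\pi_p(x) = \lVert x - p \rVert^2 - w_p,$$

zero exactly on the ball surface and negative inside.  The **regular
(weighted Delaunay) triangulation** is the dual of the power diagram of the
atoms; each simplex has an **orthosphere**, the unique sphere with zero
power to all of its weighted vertices, whose squared radius is the
simplex's *size value* (possibly negative).  Growing every ball to radius
$\sqrt{r_p^2 + \alpha}$ and taking the dual complex yields the **alpha
complex** filtration: a simplex enters the complex at its *alpha value*,
which equals its size value unless the simplex is *attached* (its
orthocentre has smaller power to a coface vertex than its own size — the
weighted Gabriel test), in which case it inherits the smallest alpha value
of its cofaces.  At $\alpha = 0$ the alpha complex represents the space
covered by the atoms, and its complement within the triangulation is a
tetrahedral decomposition of the empty space.

Channels are routed through the dual graph of that complement, the
**channel network**: one node per complement tetrahedron, one edge per
complement triangle.  Hull triangles in the complement are **mouths**;
their tetrahedra are boundary nodes, linked to a single EXTERIOR
super-node.  Components not connected to the exterior are buried **voids**
and are pruned.  Any returned channel is geometrically feasible by
construction: every triangle it crosses lies outside the alpha complex.

The triangulation is computed by incremental conflict-region insertion on
the lifted points $(x, \lVert x\rVert^2 - w)$ — equivalent to the lower
convex hull in four dimensions — with a symbolic vertex at infinity
closing the manifold.  Degenerate (cospherical, coplanar) configurations
are resolved by a deterministic joggle of $10^{-8}$ Å drawn from a fixed
seed; if the builder detects an exact tie anyway, the joggle is re-drawn
from the next seed.  All geometry (orthocentres, sizes, alpha values) is
evaluated on the original, unjoggled coordinates.  Correctness is checked
in the test suite against a brute-force oracle that enumerates all
4-subsets and applies the empty-orthosphere test directly.

## Apertures: making power-based widths robust

Size values are monotone under the face relation: the orthocentre of a
coface lies on the equal-power locus of the face, so
$\mathrm{size}(\tau) = \mathrm{size}(\sigma) + d^2 \ge
\mathrm{size}(\sigma)$ for every face $\sigma \subset \tau$.  On any
surface that is even mildly smooth, the convex hull skips over
inward-lying atoms, and the triangulation contains near-degenerate
"sliver" tetrahedra whose *empty* orthospheres are orders of magnitude
larger than any physical gap (their centres sit far outside the
molecule).  Their faces inherit those sizes and alpha values.  Any
ranking, width or position taken verbatim from such simplices is
dominated by this noise: in early experiments on the synthetic tube it
produced endpoint "mouths" with million-Ångström coordinates.

The package therefore works with **clamped apertures**.  The crossing
point of a triangle is its orthocentre when that falls inside the
triangle, otherwise the most open point of its best edge (and recursively
the better vertex).  The **aperture** is the minimum power distance over
*all* atoms at that crossing point: the squared radius of the largest
probe centred where a channel actually crosses the gap, accounting for
any blocking atom.  For well-shaped simplices — all simplices a channel
path normally visits — the aperture equals the classical size value.
Tetrahedron nodes are positioned the same way (orthocentre clamped into
the tetrahedron, falling back to the widest facet's crossing point).
This is still the paper-style "square root of power distance along the
channel": only the evaluation point is constrained to the simplex that
names it.

Network quantities follow directly:

* **edge width** = aperture of the shared triangle (floored at
  $10^{-9}\,\text{Å}^2$),
* **edge length** = the centerline polyline through the crossing point
  (node → crossing → node).  Pricing the polyline rather than the
  straight node–node distance matters because fans of complement
  tetrahedra can share nearly coincident orthocentres, which would
  otherwise allow cost-free wandering,
* **edge cost** = length / width: short, wide steps are cheap.

## Endpoints

Mouths are connected components (under shared hull edges) of open hull
triangles; a hull triangle is open at growth $\alpha$ while both its
entry alpha and its aperture exceed $\alpha$.  The scan over the closing
thresholds picks $\alpha_{max}$, the smallest $\alpha$ maximising the
mouth count (ties toward smaller $\alpha$, a conservative choice), and
the mouths are extracted there.

Each mouth is represented by one node: the tetrahedron behind the mouth
triangle with the best **access value**, the minimum of the triangle's
aperture and the widest-path width from that tetrahedron to the deep
interior (nodes with wave-front depth at least half the maximum).  The
access value is the squared radius of the largest probe that can enter
through this mouth and actually reach the inside of the molecule, which
is what makes an opening functionally important; it is the package's
operational stand-in for the persistence pairing of the opening, whose
full computation is out of scope.  Mouths whose access value is below
10% of the best are discarded as hull-film noise.  The surviving
representatives, sorted by decreasing access value and truncated to a
user chosen $k$ (default 10), form the endpoint list for pore
extraction.

Active sites are handled by the deepest-candidate rule: for each site
atom (from a user residue list or a named HETATM ligand) take the
nearest network node; among those candidates return the one with maximal
wave-front depth.  The naive alternative — nearest node to the site
centroid — fails for large ligands whose centroid sits far from the
deepest interacting pocket; the test suite contains an explicit
counter-example network.  Depth is an unweighted hop count from the
boundary, computed as a breadth-first wave front started at the exterior
node.

## Channels, pores and the transmembrane score

Channels between endpoint pairs are shortest-cost paths (Dijkstra, on
the finite subgraph — the EXTERIOR node is never a through-node).
Repeating the search after raising the used edges' costs to the
saturation constant $1 + \sum \text{costs}$ yields edge-disjoint
alternatives; a path that would reuse a saturated edge stops the
iteration.  All-pairs channels among the top-$k$ endpoint nodes are the
**important pores** (identical triangle paths collapsed; similar but not
identical channels are deliberately kept).  The **widest path tree** — a
maximum spanning tree under edge width — summarises the channel system;
pruning degree-1 nodes that are not marked important reduces it to the
paths between important nodes.

For transmembrane mode the user supplies a membrane slab (two parallel
planes; by default the structure is assumed membrane-oriented with the
normal along $z$, the usual convention of membrane-orientation
databases).  Boundary representatives project onto the normal into
$B_{in}$ / $B_{mem}$ / $B_{out}$; pores are extracted for every
$B_{in} \times B_{out}$ pair and ranked by

$$f(x) = \tfrac13\left(\frac{|x|}{\max_y |y|} +
  \frac{bn(x)}{\max_y bn(y)} + s(x)\right),$$

where $|x|$ is the centerline length, $bn(x)$ the bottleneck radius
(minimum of the radius profile), and $s(x)$ the multi-scale
straightness

$$s(S) = \frac{\sum_{d=1}^{\lfloor |S|/2 \rfloor} \sum_{i=1}^{|S|-2d}
  d\,\cos\angle(S_i, S_{i+d}, S_{i+2d})}
  {\sum_{d=1}^{\lfloor |S|/2\rfloor} \sum_{i=1}^{|S|-2d} d}$$

over a uniformly resampled centerline $S$.  Two conventions here are
deliberate.  First, $\cos\angle$ is the cosine of the *turning* angle
between the consecutive direction vectors, so a perfectly straight path
scores $+1$; reading it as the interior angle at the middle point would
give straight paths $-1$, contradicting the requirement that straight
pores are preferable.  Second, the outer sum uses the floor of $|S|/2$.
Resampling places samples at uniform arc length (spacing 1 Å by
default, capped at 512 samples), after smoothing the raw centerline
with a 3 Å boxcar (endpoints anchored): the raw tetrahedron-dual path
winds through wedge fans of the triangulation at sub-Ångström scale,
which is discretization noise rather than channel geometry —
centerline smoothing at about an atom diameter is the standard remedy
in Voronoi-based channel tools.  `smoothWindow = 0` recovers the raw
polyline.

## Bottleneck conventions

Two bottleneck numbers are reported because they answer different
questions:

* `bottleneckRadius(ch)` — the minimum of the radius profile,
  $\sqrt{\min \text{aperture}}$ along the path.  This is the
  power-distance (orthosphere) convention and the number used inside
  $f(x)$.
* `traversalProbeRadius(ch)` — the largest spherical probe that can
  follow the smoothed channel axis, measured as the minimum Euclidean
  clearance to any ball surface.  For an atom of radius $r$ at clearance
  $c$ the orthosphere radius is $\sqrt{c^2 + 2rc} > c$, so the power
  convention systematically exceeds the probe convention; on the default
  synthetic tube (constriction probe radius 2 Å, atom radius 1.7 Å)
  they differ by roughly 0.6 Å.  Probe-calibrated validation uses the
  latter.

## Profiles and volume

All profiles are real functions on $[0, d]$, parametrized by centerline
arc length.  The radius profile samples every centerline point
(tetrahedron nodes and triangle crossings, so constrictions are never
skipped); physico-chemical and conservation profiles sample one value
per path tetrahedron, the mean over the residues owning its four vertex
atoms, with residues missing from the table excluded (a node with all
four missing yields a flagged `NA` sample).  Shipped residue scales —
Kyte–Doolittle hydropathy, unit residue charge (Asp/Glu $-1$, Lys/Arg
$+1$, His $+0.5$), Zimmerman bulkiness — are plain TSV files under
`extdata/scales` and can be replaced by any user table.  Electrostatic
potential is read from an OpenDX scalar grid (the format APBS writes; z
index fastest, orthogonal axes required) and evaluated by trilinear
interpolation, which the tests require to be exact on trilinear fields.
Consecutive centerline samples can coincide geometrically (a clamped
tetrahedron apex landing on its facet's crossing point); tied arc
positions are nudged by $10^{-9}$ Å so profiles remain strictly
increasing in $t$ without dropping a simplex sample.

Channel volume uses the tetrahedral representation directly: the sum
over path tetrahedra of the tetrahedron volume minus the part covered by
any atom ball, estimated by uniform Monte-Carlo sampling inside each
tetrahedron (samples allocated by volume, at least 50 per tetrahedron)
with a fixed seed and a reported standard error.

## Synthetic structures

The generators under `makeTube()`, `makeBlob()`, `makeShell()` and
`makeBarrel()` define the study conditions for validation:

* `makeTube(length = 40, lumenRadius = 4, constrictionRadius = 2)` —
  rings of 1.7 Å balls around the z axis, two wall layers, a smooth
  pinch whose calibration ring sits exactly at
  `constrictionRadius + atomRadius` from the axis (so the largest probe
  passing the constriction has the requested radius), funnel-shaped
  mouths and jagged rims.  A quarter-Ångström of positional disorder is
  applied everywhere except the calibration ring's radial coordinate:
  perfect lattices are unlike molecular surfaces and are maximally
  degenerate for a Delaunay method, while atomically flat end caps
  would be an artifact no molecule exhibits.
* `makeBlob()` — a solid lattice sphere: no mouths, no channels.
* `makeShell()` — two concentric Fibonacci-sphere layers: a sealed
  cavity that must be pruned as a void.
* `makeBarrel(nPores)` — a lattice slab with parallel cylindrical holes:
  a multi-pore fixture.

All generators are deterministic given their seed and write standard
PDB, so external tools can cross-check them.  What passing on these
fixtures does *not* show: heterogeneous atom radii and chemistry,
side-chain-scale surface roughness, conformational variability, and the
membrane placement problem (the slab is always user input).  Validation
against experimental structures additionally depends on the van der
Waals radius table (Bondi-style here, configurable), which shifts
bottleneck radii by of order 0.1 Å.

## Numerical choices

* joggle $10^{-8}$ Å, re-drawn on precision loss; combinatorics from
  joggled, geometry from original coordinates;
* width and length floors $10^{-9}$ in network edges (so costs stay
  positive and finite even across coincident apexes);
* attachment uses strict inequality in the Gabriel test; ties are
  broken by the joggle upstream;
* endpoint ties (equal depth in active-site selection) break toward
  larger node width, then smaller tetrahedron id;
* mouth-count ties in the $\alpha_{max}$ scan break toward smaller
  $\alpha$;
* the saturation constant for edge-disjoint iteration is
  $1 + \sum \text{costs}$, which any unsaturated path undercuts.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script run on: random weighted point
sets up to $n = 50$ (against full $\binom{n}{4}$ enumeration), random
graphs up to 10 nodes (against all-simple-paths enumeration), and the
default tube (~1700 atoms, ~12000 tetrahedra), which a laptop-class
machine triangulates in a few seconds.  Real structures of a few
thousand atoms are well within reach; the conflict search is a linear
scan per insertion, so very large assemblies (tens of thousands of
atoms) will be noticeably slower.

## Known limitations

* "Persistence" of openings is the aperture/access-width proxy
  described above, not a full persistence-pairing computation.
* Mouths are recognised only on convex-hull facets; openings strictly
  inside the hull of a highly non-convex molecule are reached through
  the hull film rather than annotated as separate mouths.
* The exterior is a single super-node; per-mouth exterior geometry is
  recovered through mouth triangles only.
* No automatic membrane placement; transmembrane classification is
  only as good as the supplied slab.
* Electrostatic profiles inherit every caveat of the upstream grid
  calculation and should be read qualitatively.

## A worked example

```{r example, eval = FALSE}
tube <- makeTube(length = 40, lumenRadius = 4, constrictionRadius = 2)
res <- extractPores(tube, k = 10, membrane = membraneSlab(10, 30))
top <- res$tmPores[[1]]
top
radiusProfile(top)
traversalProbeRadius(top)   # ~2 A: the calibrated constriction
channelVolume(top, mcSamples = 50000, seed = 1)
```
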