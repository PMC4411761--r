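# AlphaPore

Extraction, ranking and profiling of channels and pores in biomolecules,
built on the alpha complex of the van der Waals ball model.

Channels — the empty-space pathways that carry ions, substrates and
solvent through a protein — are found here as paths of tetrahedra in the
complement of the alpha complex at α = 0.  Because every crossed triangle
lies outside the complex, each reported channel is geometrically
feasible by construction, and the tetrahedral representation carries the
channel volume and a centerline in one object.  The package is aimed at
structural bioinformaticians who want reproducible, scriptable channel
analysis (the kind of questions tools in the HOLE/MOLE/CAVER family
answer) with full access to the intermediate objects.

## Method in brief

Atoms become weighted points (weight = vdW radius², Bondi-style table,
configurable); their regular (weighted Delaunay) triangulation is
computed by incremental insertion on the lifted points, and every
simplex gets its orthosphere, size value and alpha value.  The dual
graph of the complement at α = 0 is the channel network: nodes at
tetrahedron crossing points, edges across complement triangles with
cost = length / width, where the width is the clamped aperture — the
minimum power distance over all atoms at the point where the channel
crosses the gap.  Mouths (complement hull triangles) are scanned over α
for the mouth-count maximum, one representative node per mouth is chosen
by widest interior access, and shortest-cost (Dijkstra) paths between
representatives give the pores.  With a membrane slab, pores from the
inner to the outer side are ranked by

    f(x) = (|x| / max|y| + bn(x) / max bn(y) + s(x)) / 3

with |x| the length, bn(x) the bottleneck radius and s(x) a multi-scale
straightness of the resampled centerline.  Radius, hydropathy, charge,
bulkiness, conservation and electrostatic (OpenDX/APBS grid) profiles
are computed along the centerline; channels export as JSON, CSV, SVG
box diagrams and PyMOL scripts.  `vignette("alphapore-methods")` has the
full model and all design decisions.

## Worked example

A synthetic hollow tube, 40 Å long with a 4 Å lumen pinched to a 2 Å
constriction, analysed as a membrane pore (slab at z in [10, 30] Å):

```r
library(AlphaPore)
tube <- makeTube(length = 40, lumenRadius = 4, constrictionRadius = 2)
res  <- extractPores(tube, k = 10, membrane = membraneSlab(10, 30))
res$network
#> ChannelNetwork (alpha = 0): 4537 nodes (162 boundary), 7430 interior
#>   edges, 189 mouth triangles, 0 void component(s) pruned
res$endpoints
#> EndpointSet: 2 boundary representative(s), 2 mouth(s) at alpha_max = 0 A^2
top <- res$tmPores[[1]]
top
#> Channel [transmembrane]: 113 tetrahedra, length 50.03 A,
#>   bottleneck radius 2.569 A, score 0.9989
traversalProbeRadius(top)
#> [1] 1.88307
channelVolume(top, mcSamples = 50000, seed = 1)$volume
#> [1] 1087.76
```

The two mouths are the tube ends; the single transmembrane pore runs
along the axis.  `bottleneckRadius` (2.57 Å) is the power-distance
(orthosphere) convention used in the score; `traversalProbeRadius`
(1.88 Å) is the largest spherical probe that can follow the channel
axis and recovers the 2 Å constriction the generator was built with.
Profiles come from `radiusProfile(top)`, `physchemProfile(top,
scaleTable("hydropathy"))`, `conservationProfile()`,
`electrostaticProfile()`; `exportPyMOL(top, "pore.pml")` writes the
union-of-balls view.

A command-line front end over the same functions is installed at
`inst/scripts/alphapore.R`:

```sh
Rscript inst/scripts/alphapore.R --pdb protein.pdb --out run1 \
        --membrane-z -15,15 --conservation consurf.tsv
```

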