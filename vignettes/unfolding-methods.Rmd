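---
title: "Intrinsic coordinates and unfolding of the hippocampal ribbon: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic coordinates and unfolding of the hippocampal ribbon: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldcoords)
```

## The problem

The hippocampus is not a blob but a folded archicortical sheet, 0.5–2 mm
thick, whose folding pattern (curl, digitations) differs between
individuals.  Treating it as a sheet gives every grey-matter point three
intrinsic coordinates: position along the long axis (anterior–posterior,
AP), position across the sheet from the neocortical side to the dentate
gyrus (proximal–distal, PD), and laminar depth (inner–outer, IO).  Indexing
tissue by these coordinates instead of by scanner coordinates aligns
subjects topologically: two hippocampi with different folding agree at
equal intrinsic coordinates, the way two differently tangled wires agree at
equal fractions of their length.

`unfoldcoords` computes these coordinates from a voxel tissue-class
labelmap, maps tissue into a standardized "unfolded" rectangular prism,
and derives everything downstream of that mapping: surfaces with
positional vertex correspondence, subfield labels applied identically to
all subjects in unfolded space, and vertex-wise morphometry.

## Coordinates as harmonic fields

Each axis is the solution of Laplace's equation over the grey-matter (GM)
voxel domain with Dirichlet boundaries at anatomical endpoints:

* **AP**: 0 at the boundary with the hippocampal–amygdalar transition area
  (HATA), 1 at the indusium griseum (IndGris);
* **PD**: 0 at the medial temporal lobe cortex (MTLc), 1 at the dentate
  granule cell layer;
* **IO**: 0 at the SRLM (the high-myelin lamina lining the inner fold,
  plus cyst inclusions, which interrupt GM the same way), 1 at the outer
  boundary (pial label plus background by default; a pial-only option
  exists because the anatomical definition of "outer" is a modelling
  choice).

All other domain borders are no-flux (Neumann): the neighbor is simply
omitted from the discrete average, so the field spans the full 0–1 range
between its designated endpoints and nowhere else.

Numerically we use a 6-neighbor stencil (18/26 selectable), solved by
successive over-relaxation Gauss–Seidel sweeps with `omega = 1.8`,
stopping when the largest update falls below `tol = 1e-5` (cap 10,000
sweeps, logged).  Sweeps start from a geodesic initialization
`d_src / (d_src + d_snk)` (multi-source BFS distances within the domain),
which cuts the iteration count substantially; the converged field is
independent of the initialization to within the tolerance.

One discretization choice matters for accuracy: Dirichlet values are taken
to sit on the *face* between a boundary voxel and the domain, encoded as
weight 2 for boundary neighbors in the weighted mean.  With values at
boundary-voxel *centers* instead, every boundary acquires a half-voxel
offset, and a 1.2 mm sheet sampled at 0.3 mm gains roughly 0.3 mm of
apparent thickness (we measured ~15% before adopting the face convention,
~2% after).  On a 1D slab of n voxels the converged profile is exactly
`(i + 0.5) / n`.

## Equivolumetric depth

On a curved sheet, equal-distance laminae misplace layers: the outer
surface of a gyrus has more area than the inner, so a layer occupying a
fixed volume fraction sits at different fractional distances depending on
curvature.  The IO Laplace fraction `alpha` is therefore replaced by the
equivolumetric depth

\[
\rho = \frac{-A_{in} + \sqrt{\alpha A_{out}^2 + (1-\alpha) A_{in}^2}}{A_{out} - A_{in}},
\]

where `A_in`, `A_out` are the local inner and outer surface areas of the
column through the voxel.  When the areas are equal this reduces to
`rho = alpha` (implemented explicitly for `|A_out - A_in| < 1e-9 A_in`);
the endpoints 0 and 1 are always preserved, and the map is a monotone
bijection of [0,1] for any positive areas.  For a 2D annulus with radii
1 and 2 and `alpha = 1/3` the analytic value is `sqrt(2) - 1`, which the
implementation reproduces to machine precision.  Column areas are
estimated per (AP, PD) cell on a coarse 64 x 32 unfolded grid from vertex
areas of provisional inner/outer surfaces, and looked up bilinearly per
voxel; the raw Laplace IO field can be kept with `io_mode = "laplace"`.

## The unfolded prism and the warps

Normalized (AP, PD, IO) triples scale to a standardized rectangular prism
of 256 x 128 x 16 voxels at 0.15625 mm isotropic (40 x 20 x 2.5 mm; the
2:1 AP:PD aspect reflects that the structure is longer than it is wide).
The dentate gyrus gets its own 256 x 32 x 16 prism: it is a separate sheet
wrapped around the CA4 terminus, topologically perpendicular to the rest
of the cortical mantle, so its PD and IO axes are swapped relative to the
hippocampus proper.  The prism origin is (0,0,0) mm with a diagonal
affine; this origin is a package convention.

**Native to unfolded**: each GM voxel's displacement is its scaled
unfolded coordinate minus its native world coordinate.  The field is made
dense (standard warping tools expect that) by nearest-GM front
propagation followed by a 1-voxel Gaussian smoothing of the extrapolated
region, with GM values kept exact.

**Unfolded to native**: GM voxels are scattered samples — position =
scaled unfolded coordinate, value = native world coordinate — evaluated
on the regular unfolded grid.  We use deterministic k-nearest-neighbour
moving-least-squares interpolation: for each grid point, a
distance-weighted affine fit to the k = 16 nearest samples (grid-hashed
neighbour search; the neighbourhood grows automatically up to 4k when the
nearest samples are degenerate, e.g. coplanar near the laminar faces).
This evaluator is exact for affine coordinate maps, smooth, and extends
past the sample cloud by the local affine model, so the grid is finite
everywhere.  A Delaunay-based piecewise-linear evaluator would be the
other natural choice; the MLS form was chosen because it needs no
triangulation machinery, is deterministic by construction, and meets the
same accuracy targets (forward/backward round trips on the phantom stay
well under one unfolded voxel at the 95th percentile).

Warps serialize as ITK-convention displacement NIfTIs: a 5D
`(X, Y, Z, 1, 3)` volume, displacement-field intent, vectors in LPS
physical convention (the first two RAS components negated), stored double
precision so the round trip is bit-exact.  A plain 4D RAS variant exists
behind a flag.

## Surfaces and decimation

Unfolded tessellations are uniform grids over the AP x PD rectangle with
each quad split along the (+AP, +PD) diagonal.  The legacy `unfoldiso`
grids are 254 x 126 (32,004 vertices) for the hippocampus and 254 x 30
(7,620) for the DG; they are used as-is, with no decimation, so vertices
are uniform in unfolded space and distorted in native space.

The mm-spacing presets (0.5, 1, 2 mm) are defined by target *native*
spacing: the tessellation is decimated against the subject's native
midthickness geometry until the median native edge length reaches the
target.  Decimation collapses the shortest native-space edge into its
surviving endpoint, with three guards: interior vertices are always the
ones removed (boundary vertices only collapse along the boundary), a link
condition keeps the sheet 2-manifold, and a collapse is rejected if it
would create a degenerate or flipped triangle in the unfolded parameter
plane (which keeps winding consistent and unfolded vertex areas positive)
or an edge longer than 2.2x the target (which prevents one vertex from
cascade-absorbing its neighbourhood — without this bound a uniform mesh
collapses wavefront-style into one side).  The stop criterion re-checks
the median after about 2% of live vertices.  We start the presets from
the 254 x 126 grid rather than a denser one: at spacing-defined targets
the result is the same and the work is a quarter.

Inner, midthickness and outer layers instantiate the same (AP, PD)
vertex set at IO = 0, 0.5, 1 and map each through the unfolded-to-native
warp, so all three layers share the triangle array bit-exactly and
vertices correspond positionally across layers and subjects.

## Morphometry

* **Thickness**: Euclidean distance between corresponding inner and outer
  vertices (the layers share vertex indices by construction).  Not
  defined for the DG, whose laminar axis is the swapped one.
* **Smoothing**: iterative neighbourhood averaging,
  `v <- 0.4 v + 0.6 mean(neighbours)` for 100 iterations (the defaults),
  applied to the midthickness surface before curvature.
* **Mean curvature**: cotangent-Laplacian mean-curvature normal with
  Meyer mixed-Voronoi vertex areas (obtuse triangles fall back to T/2,
  T/4), signed positive when the curvature vector points along the
  area-weighted vertex normal; the sign flips under mirroring.  On a
  subdivided icosphere of radius 5 the estimate is within 0.01% of 1/r.
* **Vertex area**: the arithmetic mean of incident triangle areas.  A
  barycentric (third-of-sum) definition is more common, but the mean is
  used deliberately; the gyrification ratio is insensitive to the common
  factor on matched triangulations.
* **Gyrification**: native vertex area / unfolded vertex area at
  corresponding midthickness vertices.
* **Sampling**: trilinear interpolation of any co-registered volume at
  vertex positions; out-of-volume vertices are NaN with a count.

Curvature is computed on the *smoothed* midthickness surface; where a
pre- or post-smoothing surface should be used is genuinely ambiguous in
common practice, and we document our choice rather than leave it
implicit.

## Subfields

An unfolded-plane label image is applied identically to every subject:
vertex labels by nearest-pixel lookup of (AP, PD), volumetric labels by
the same lookup per GM voxel (an independent per-voxel indexing oracle in
the tests reproduces the implementation voxel-for-voxel), with DG voxels
given their own label and NaN-coordinate voxels falling back to the
nearest coordinate-bearing voxel.  Topology checks count connected
components per label on the vertex graph, flag adjacencies that skip the
canonical Sub - CA1 - CA2 - CA3 - CA4 - DG ordering, and verify that each
band reaches both AP extremes.

The package ships a *schematic* five-band atlas (PD fractions 0.30, 0.32,
0.10, 0.15, 0.13 for Sub, CA1, CA2, CA3, CA4) because a
histology-derived unfolded atlas is an external artifact; any labelled
unfolded image drops in via `read_atlas()`, changing labels but never
geometry.

## Template shape injection

Segmentations can carry topological defects (holes, missed tissue) that
break the coordinate solve.  Injection registers an idealized template
labelmap to the subject's labelmap and replaces the segmentation with the
deformed template: registration is driven by label overlap, not image
intensity — channels are Gaussian-smoothed one-hot label masks and the
cost is summed per-channel MSE, minimized when identical labels overlap.
The optimizer is a multi-resolution (factors 4/2/1) demons scheme with
the symmetric (ESM) per-voxel normalized force, Gaussian smoothing of
each update (1.5 mm) and of the accumulated field (0.2 mm), and a
monotone line search on the step scale, 150 iterations per level.  The
same deformation carries the template's precomputed DG coordinate fields
into subject space — the DG is often thinner than one voxel, so its
fields come from the template rather than a direct solve (a fallback
solver on an upsampled DG domain exists behind a flag, but injection is
the default and recommended path).

The regularization strengths are free parameters with no canonical
values; ours were calibrated once against the synthetic recovery task the
test suite encodes (a sinusoidal deformation of two voxels amplitude must
be recovered with per-label Dice at least 0.95) and then frozen.  The
channel smoothing matters most: at 1 mm the 1.4-voxel-thin SRLM and pial
labels blur into their surroundings and recovery saturates near Dice
0.84; at 0.3 mm all labels recover to 0.98+.

## The phantom

The synthetic generator rasterizes a parametric sheet — arc of
`curl_turns` turns, sinusoidal digitations along AP, configurable
thickness/length/width — into the 128 x 256 x 128 cropped grid at 0.3 mm,
with the full tissue inventory attached by parameter bands: HATA/IndGris
caps at the AP ends, an MTLc strip proximally, a DG granule band
distally, SRLM lining the concave face, pial on the convex face, and
optional flattened-ellipsoid cysts strictly inside GM.  The generative
(u, v, w) of the sample nearest each voxel center are stored as
ground-truth AP/PD/depth, and the analytic mid-surface area (numerical
integration of the parametric area element) serves as the reference for
the global gyrification ratio.  Default parameters are a half-turn curl,
three digitations of 1 mm, a 1.2 mm-thick 32 x 16 mm sheet — scaled like
the anatomy (thickness within the 0.5–2 mm anatomical range), with the
component test suite using a 16 x 9 mm sheet in a 64 x 96 x 64 grid for
speed.

What the phantom does and does not emulate: it has the right topology
(one folded sheet with all boundary tissues in the right adjacency), the
right scale, curvature and digitations, but no anatomically realistic
shape variation, no segmentation noise, and perfectly clean labels.
Passing tests therefore demonstrate correctness of the machinery
(fields, warps, surfaces, metrics) under known ground truth — not
robustness to real segmentation quality, which is what the QC flagging
and template injection are for.

## Quantization limits (what the tests assert, and why)

Several properties are bounded by the 0.3 mm voxel size rather than by
the implementation, and the tests state them at the attainable level:

* Per-band subfield voxel counts: the PD extent is ~22–38 voxel layers,
  tissue boundaries are defined only to sub-voxel precision, and on a
  curled sheet the PD Laplace field legitimately deviates from normalized
  arc length by ~0.02 (equipotentials tilt with laminar depth).  One
  flipped layer changes the narrow CA2 band by ~30%, so counts are
  asserted against the truth-quantized oracle to within one PD layer of
  voxels.
* Vertex/voxel label agreement: a vertex and its containing voxel differ
  in (AP, PD) by up to half a voxel's worth of coordinate, so
  disagreement concentrates within half a voxel of band edges; agreement
  is asserted at 99% away from edges and 95% overall.
* Re-injection stability: with labels 1.4 voxels thick, a 0.02-voxel
  boundary error already costs 1% Dice, capping
  `inject(inject(x))` vs `inject(x)` per-label Dice near 0.94; stability
  is asserted at 0.9.

## Problem sizes and determinism

The test suite runs the full default phantom (13.5k GM voxels, 32,004 and
1.7k vertex surfaces) once end-to-end and the component-scale phantom for
everything else; the acceptance script reruns the default phantom
pipeline, both Laplace oracles, the morphometry oracles and one injection
recovery, completing in about 90 seconds on one CPU.  Everything is
deterministic given the configuration seed: the phantom threads its seed
through cyst placement only, solvers are fixed-order sweeps, neighbour
searches and decimation use fixed tie-breaking, and repeated pipeline
runs produce bit-identical vertex arrays and label volumes.

## Known limitations

* Dense warps are smooth but carry no diffeomorphic guarantee outside
  GM; the injection deformation is checked for positive Jacobian on
  labelled tissue only.
* The schematic atlas is a synthetic stand-in; real analyses should drop
  in a histology-derived unfolded atlas.
* Surface placement inherits the voxelization of the input labelmap;
  sub-voxel boundary effects of order 0.1–0.2 voxels remain (thickness on
  the default phantom recovers to ~2.6%).
* No preprocessing: inputs must already be cropped, hippocampus-oblique
  tissue labelmaps; segmentation itself (the neural-network stage of the
  original tool) is out of scope.
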