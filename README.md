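# unfoldcoords

Topological unfolding of hippocampal grey matter in R.

The hippocampus is a folded cortical sheet ("ribbon"), 0.5–2 mm thick,
whose folding differs between individuals. `unfoldcoords` takes a voxel
tissue-class labelmap of the hippocampus (grey matter plus the boundary
tissues SRLM, MTLc, pial, HATA, indusium griseum, cysts and the dentate
granule layer) and computes an intrinsic coordinate system over the grey
matter by solving Laplace's equation along three anatomical axes:

- **AP** (anterior–posterior): 0 at the HATA boundary, 1 at the indusium
  griseum;
- **PD** (proximal–distal): 0 at the medial temporal lobe cortex, 1 at the
  dentate granule layer;
- **IO** (inner–outer, laminar): 0 at the SRLM, 1 at the outer boundary —
  by default replaced with the equivolumetric depth
  `rho = (-A_in + sqrt(alpha A_out^2 + (1-alpha) A_in^2)) / (A_out - A_in)`,
  which preserves laminar volume fractions under curvature.

Scaling (AP, PD, IO) to a standardized 256 × 128 × 16 prism at
0.15625 mm ("unfolded space"; the dentate gyrus gets its own
256 × 32 × 16 prism with PD and IO swapped) yields bidirectional warps
between native and unfolded space, serialized as ITK-convention
displacement NIfTIs. Everything downstream rides on those warps:

- folded/unfolded **surface meshes** (inner, midthickness, outer) with
  positional vertex correspondence across layers and subjects, at the
  legacy `unfoldiso` density (254 × 126 = 32,004 vertices; DG
  254 × 30 = 7,620) or decimated to 0.5/1/2 mm native spacing;
- **subfield labels** (Sub, CA1–CA4, DG) applied identically to all
  subjects in unfolded space, as vertex labels and filled label volumes,
  with topology checks (single components, canonical band ordering, full
  AP extent);
- vertex-wise **morphometry**: thickness, mean curvature (on a
  neighbourhood-smoothed midthickness, strength 0.6, 100 iterations),
  gyrification (native / unfolded vertex-area ratio), and sampling of
  quantitative volumes onto surfaces;
- **template shape injection**: fluid multi-channel demons registration of
  an idealized labelmap to the subject (label-MSE cost on smoothed one-hot
  channels) to repair segmentation defects and carry precomputed DG
  coordinate fields into subject space;
- **QC flagging**: Dice overlap of the grey-matter segmentation against a
  reference mask, flagged strictly below 0.7;
- a parametric **phantom generator** — a curled, digitated sheet with the
  full tissue inventory and analytic ground-truth coordinates — used for
  all validation.

The intended users are neuroimaging researchers who already have
hippocampal tissue segmentations (manual or from a segmentation network)
in the cropped hippocampus-oblique space and want surface-based,
topologically aligned analyses.

## Worked example

Generate a phantom, unfold it, and measure it:

```r
library(unfoldcoords)

params <- phantom_params(length = 16, width = 9, thickness = 1.2,
                         curl_turns = 0.4, n_digitations = 2,
                         digitation_amplitude = 0.6,
                         grid_shape = c(64L, 96L, 64L), seed = 7)
phantom <- generate_phantom(params)
phantom$labelmap
#> <tissue_labelmap> 64 x 96 x 64 voxels @ 0.3 x 0.3 x 0.3 mm, hemi-R
#>        GM      SRLM      cyst DGgranule      MTLc      pial      HATA   IndGris
#>      3754      2271        30       445       586      3607       393       360

validate_labelmap(phantom$labelmap)
#> <validation_report>
#>   missing labels: none
#>   GM components: 1

fields <- compute_coord_fields(phantom$labelmap)
fields
#> <coord_fields> 3754 domain voxels, io_mode=equivolume

spec <- unfolded_space_spec("hipp")
warp_u2n <- build_unfolded_to_native(fields, phantom$labelmap, spec)
layers <- build_layer_surfaces(spec, warp_u2n, "0p5mm")
layers$midthickness
#> <surface_mesh> 493 vertices, 900 triangles, native space, den-0p5mm, midthickness

thickness(layers$inner, layers$outer)
#> <metric_map> thickness [mm], n=493, mean=1.1728, sd=0.056057
```

The recovered mean thickness (1.17 mm) is the generative 1.2 mm to within
the voxelization; 493 vertices at 0.5 mm spacing is what a
16 × 9 mm sheet supports. Subfields and QC:

```r
atlas <- make_schematic_atlas()
labs <- label_vertices(atlas, layers$midthickness)
check_topology(labs, layers$midthickness, label_names = atlas$label_names)
#> <topology_report>
#>   components per label: Sub=1, CA1=1, CA2=1, CA3=1, CA4=1
#>   adjacency violations: none
#>   full AP extent: Sub, CA1, CA2, CA3, CA4

flag_low_dice(phantom$labelmap$data == 1, phantom$labelmap$data == 1)
#> <qc_result> dice=1 ok (threshold 0.7)
```

Every subfield is a single band spanning the full AP extent — the
topological guarantee that volumetric atlas methods do not give.
`run_pipeline()` chains all stages (validate → inject → fields → warps →
surfaces → subfields → morphometry → QC) and writes BIDS-derivatives-style
NIfTI/GIfTI outputs plus a QC report.

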