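# Unfolded subfield atlas application, volumetric filling and topology.

test_that("schematic atlas builds PD bands spanning the full AP extent", {
  a5 <- make_schematic_atlas(rep(0.2, 5))
  counts <- table(a5$label_image)
  expect_length(counts, 5)
  # five equal bands: pixel counts equal within one PD column
  expect_lte(diff(range(counts)), nrow(a5$label_image))
  # every band present at both AP extremes (rows 1 and 256)
  expect_setequal(unique(a5$label_image[1, ]), 1:5)
  expect_setequal(unique(a5$label_image[nrow(a5$label_image), ]), 1:5)
  uni <- make_schematic_atlas(c(Sub = 1))
  expect_true(all(uni$label_image == 1L))
  expect_error(make_schematic_atlas(c(0.5, 0.4)), "sum to 1")
})

test_that("atlas I/O round-trips through 2D NIfTI", {
  atlas <- make_schematic_atlas()
  f <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(array(atlas$label_image, c(dim(atlas$label_image), 1L)),
                     f, affine = diag(4), datatype = "int16")
  back <- read_atlas(f, atlas$label_names)
  expect_identical(back$label_image, atlas$label_image)
})

test_that("vertex labelling matches band fractions on the unfoldiso mesh", {
  atlas <- make_schematic_atlas()
  mesh <- make_grid_mesh(254, 126)
  labs <- label_vertices(atlas, mesh)
  expect_length(labs, 32004L)
  frac <- as.vector(table(labs)) / length(labs)
  bands <- c(0.30, 0.32, 0.10, 0.15, 0.13)
  expect_true(all(abs(frac - bands) < 0.01))
  # single-label atlas labels everything
  uni <- make_schematic_atlas(c(Sub = 1))
  expect_true(all(label_vertices(uni, mesh) == 1L))
  # all labels reach both AP extremes
  ap <- mesh$unfolded_coords[, 1]
  for (v in 1:5) {
    expect_true(any(labs == v & ap == 0))
    expect_true(any(labs == v & ap == 1))
  }
})

test_that("volumetric filling matches a per-voxel lookup oracle and partitions GM", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  atlas <- make_schematic_atlas()
  vol <- fill_volumetric_subfields(atlas, f, ph$labelmap)
  # independent per-voxel oracle: direct (AP, PD) -> pixel indexing
  gm <- which(f$domain_mask)
  ap <- pmin(pmax(f$ap[gm], 0), 1); pd <- pmin(pmax(f$pd[gm], 0), 1)
  d <- dim(atlas$label_image)
  i <- pmin(pmax(floor(ap * d[1]) + 1L, 1L), d[1])
  j <- pmin(pmax(floor(pd * d[2]) + 1L, 1L), d[2])
  oracle <- atlas$label_image[cbind(i, j)]
  expect_identical(vol$data[gm], oracle)
  # GM voxel count preserved across subfield labels
  expect_identical(sum(vol$data[gm] > 0L), length(gm))
  # DG voxels get the DG label
  dgm <- unfoldcoords:::label_mask(ph$labelmap, "DGgranule")
  expect_true(all(vol$data[dgm] == max(atlas$label_names) + 1L))
})

test_that("NaN-coordinate voxels fall back to the nearest coordinate", {
  ph <- get_phantom()  # includes a cyst: GM interior with NaN neighbours
  fld <- memo("fields_cyst", compute_coord_fields(ph$labelmap))
  # punch NaN into a few GM coordinate voxels to exercise the fallback
  f2 <- fld
  gmv <- which(f2$domain_mask)[1:5]
  f2$ap[gmv] <- NaN
  vol <- fill_volumetric_subfields(make_schematic_atlas(), f2, ph$labelmap)
  expect_identical(attr(vol, "n_fallback"), 5L)
  expect_true(all(vol$data[gmv] > 0L))
})

test_that("phantom subfield volumes follow the generative band volumes", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  atlas <- make_schematic_atlas()
  vol <- fill_volumetric_subfields(atlas, f, ph$labelmap)
  gm <- f$domain_mask
  counts <- table(factor(vol$data[gm], levels = 1:5))
  # phantom-truth oracle: band occupancy of the generative PD parameter,
  # quantized on the same voxel grid.  The voxelized PD boundary position is
  # only defined to sub-voxel precision, so each band count can differ from
  # the generative count by up to one PD voxel layer.
  edges <- cumsum(c(0, 0.30, 0.32, 0.10, 0.15, 0.13))
  truth_band <- findInterval(pmin(pmax(ph$truth$true_pd[gm], 0), 1), edges,
                             rightmost.closed = TRUE)
  truth_counts <- table(factor(truth_band, levels = 1:5))
  p <- small_params()
  n_pd_layers <- 0.72 * p$width / p$voxel_size
  layer_voxels <- sum(gm) / n_pd_layers
  expect_true(all(abs(as.vector(counts) - as.vector(truth_counts)) <=
                    layer_voxels))
})

test_that("topology report finds single bands, splits and shuffles", {
  atlas <- make_schematic_atlas()
  mesh <- make_grid_mesh(128, 64)  # smaller grid, same structure
  labs <- label_vertices(atlas, mesh)
  names_tab <- atlas$label_names
  topo <- check_topology(labs, mesh, label_names = names_tab)
  expect_true(all(topo$components_per_label == 1L))
  expect_length(topo$adjacency_violations, 0)
  expect_true(all(topo$full_ap_extent))

  # artificially split CA2 into two islands
  labs2 <- labs
  ca2 <- which(labs2 == names_tab["CA2"])
  ap <- mesh$unfolded_coords[ca2, 1]
  labs2[ca2[ap > 0.4 & ap < 0.6]] <- names_tab["CA1"]
  topo2 <- check_topology(labs2, mesh, label_names = names_tab)
  expect_identical(unname(topo2$components_per_label["CA2"]), 2L)

  # shuffled labels violate the canonical ordering
  set.seed(1)
  labs3 <- sample(labs)
  topo3 <- check_topology(labs3, mesh, label_names = names_tab)
  expect_gt(length(topo3$adjacency_violations), 0)
})

test_that("vertex labels agree with volumetric labels at vertex positions", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  atlas <- make_schematic_atlas()
  vol <- fill_volumetric_subfields(atlas, f, ph$labelmap)
  layers <- get_layers_iso()
  labs <- label_vertices(atlas, layers$midthickness)
  vox <- round(world_to_voxel(ph$labelmap$affine,
                              layers$midthickness$vertices)) + 1L
  lin <- vox[, 1] + dim(vol$data)[1] * (vox[, 2] - 1L) +
    prod(dim(vol$data)[1:2]) * (vox[, 3] - 1L)
  vol_lab <- vol$data[lin]
  in_gm <- f$domain_mask[lin]
  agree <- mean(labs[in_gm] == vol_lab[in_gm])
  expect_gte(agree, 0.95)
  # vertices further than half a voxel (in PD units) from a band edge must
  # agree almost surely; disagreement is confined to the quantization zone
  pd <- layers$midthickness$unfolded_coords[, 2]
  half_vox <- 0.5 * mean(ph$labelmap$voxel_size) /
    (0.72 * small_params()$width) * 1.5
  edges <- cumsum(c(0.30, 0.32, 0.10, 0.15))
  near_edge <- vapply(pd, function(p) any(abs(p - edges) < half_vox),
                      logical(1))
  interior <- in_gm & !near_edge
  expect_gte(mean(labs[interior] == vol_lab[interior]), 0.99)
})

test_that("swapping the atlas changes labels but never geometry", {
  layers <- get_layers_iso()
  a1 <- make_schematic_atlas()
  a2 <- make_schematic_atlas(c(Sub = 0.2, CA1 = 0.2, CA2 = 0.2,
                               CA3 = 0.2, CA4 = 0.2))
  l1 <- label_vertices(a1, layers$midthickness)
  l2 <- label_vertices(a2, layers$midthickness)
  expect_false(identical(l1, l2))
  # geometry untouched by construction: labelling is read-only
  expect_identical(layers$midthickness$vertices,
                   get_layers_iso()$midthickness$vertices)
})

test_that("atlas lookup rejects out-of-extent meshes", {
  atlas <- make_schematic_atlas()
  m <- make_grid_mesh(10, 10)
  m$unfolded_coords[1, 1] <- 1.5
  expect_error(label_vertices(atlas, m), "extent")
})
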