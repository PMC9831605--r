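# Native <-> unfolded warps: prism scaling, closed-form affine checks,
# round-trip accuracy, ITK serialization, and application semantics.

test_that("scale_to_unfolded maps unit-cube corners to the prism extent", {
  spec <- unfolded_space_spec("hipp")
  expect_equal(as.vector(scale_to_unfolded(c(0, 0, 0), spec)), c(0, 0, 0))
  expect_equal(as.vector(scale_to_unfolded(c(1, 1, 1), spec)),
               c(40, 20, 2.5))
  dg <- unfolded_space_spec("dg")
  expect_equal(as.vector(scale_to_unfolded(c(0.5, 0.5, 0.5), dg)),
               c(256, 32, 16) * 0.15625 / 2)
  expect_error(scale_to_unfolded(c(1.2, 0, 0), spec), "outside")
})

test_that("unfolded space specs carry the standardized geometry", {
  spec <- unfolded_space_spec("hipp")
  expect_identical(spec$shape, c(256L, 128L, 16L))
  expect_equal(spec$voxel_size, 0.15625)
  expect_equal(spec$extent[1] / spec$extent[2], 2)  # 2:1 AP:PD aspect
  expect_equal(unfolded_space_spec("dg")$shape, c(256L, 32L, 16L))
  expect_equal(spec$extent, spec$shape * spec$voxel_size)
})

test_that("axis-aligned prism with linear fields gives the closed-form affine warp", {
  pr <- make_affine_prism()
  spec <- unfolded_space_spec("hipp")
  w_fwd <- build_native_to_unfolded(pr$fields, pr$lm, spec)
  # forward: on GM voxels, displacement must equal affine map - identity
  gm_idx <- which(pr$lm$data == 1L, arr.ind = TRUE)
  world <- voxel_to_world(pr$lm$affine, gm_idx - 1L)
  coords <- cbind(pr$fields$ap[pr$lm$data == 1L],
                  pr$fields$pd[pr$lm$data == 1L],
                  pr$fields$io[pr$lm$data == 1L])
  expected <- scale_to_unfolded(coords, spec)
  got <- world + t(apply(gm_idx, 1, function(ijk)
    w_fwd$displacement[ijk[1], ijk[2], ijk[3], ]))
  expect_lt(max(abs(got - expected)), 1e-9)

  # backward: the MLS evaluation reproduces the inverse affine exactly
  w_bwd <- build_unfolded_to_native(pr$fields, pr$lm, spec)
  # analytic inverse: unfolded (u1,u2,u3) -> voxel -> world
  qs <- voxel_to_world(spec$affine, voxel_grid(spec$shape))
  sel <- sample(nrow(qs), 500)
  uc <- sweep(qs[sel, ], 2, spec$extent, "/")
  vox <- cbind(min(pr$gm$x) - 1 + uc[, 2] * (length(pr$gm$x) - 1),
               min(pr$gm$y) - 1 + uc[, 1] * (length(pr$gm$y) - 1),
               min(pr$gm$z) - 1 + uc[, 3] * (length(pr$gm$z) - 1))
  # voxel order: pd ran along x, ap along y, io along z
  vox <- vox[, c(1, 2, 3)]
  vox_sorted <- cbind(min(pr$gm$x) - 1 + uc[, 2] * (length(pr$gm$x) - 1),
                      min(pr$gm$y) - 1 + uc[, 1] * (length(pr$gm$y) - 1),
                      min(pr$gm$z) - 1 + uc[, 3] * (length(pr$gm$z) - 1))
  expected_nat <- voxel_to_world(pr$lm$affine, vox_sorted)
  got_nat <- transform_points(w_bwd, qs[sel, ])
  expect_lt(max(abs(got_nat - expected_nat)), 1e-6)
})

test_that("phantom GM lands inside the unfolded prism and round-trips within a voxel", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  spec <- unfolded_space_spec("hipp")
  w_n2u <- get_warp_n2u()
  gm_idx <- which(f$domain_mask, arr.ind = TRUE)
  world <- voxel_to_world(ph$labelmap$affine, gm_idx - 1L)
  img <- transform_points(w_n2u, world)
  pad <- 1e-6
  expect_true(all(img[, 1] >= -pad & img[, 1] <= spec$extent[1] + pad))
  expect_true(all(img[, 2] >= -pad & img[, 2] <= spec$extent[2] + pad))
  expect_true(all(img[, 3] >= -pad & img[, 3] <= spec$extent[3] + pad))

  # round trip unfolded -> native -> unfolded on interior points
  w_u2n <- get_warp_u2n()
  set.seed(11)
  n <- 3000
  uc <- cbind(runif(n, 0.1, 0.9), runif(n, 0.1, 0.9), runif(n, 0.2, 0.8))
  start <- scale_to_unfolded(uc, spec)
  nat <- transform_points(w_u2n, start)
  back <- transform_points(w_n2u, nat)
  err_vox <- sqrt(rowSums((back - start)^2)) / spec$voxel_size
  expect_lt(quantile(err_vox, 0.95), 1)
})

test_that("warp construction is deterministic", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  w1 <- build_unfolded_to_native(f, ph$labelmap)
  w2 <- build_unfolded_to_native(f, ph$labelmap)
  expect_identical(w1$displacement, w2$displacement)
  n1 <- build_native_to_unfolded(f, ph$labelmap)
  n2 <- build_native_to_unfolded(f, ph$labelmap)
  expect_identical(n1$displacement, n2$displacement)
})

test_that("ITK warp serialization round-trips and encodes LPS on disk", {
  w <- get_warp_u2n()
  f <- tempfile(fileext = ".nii.gz")
  write_itk_warp(w, f)
  back <- read_itk_warp(f, "unfolded_to_native")
  expect_identical(back$displacement, w$displacement)
  expect_equal(back$ref_affine, w$ref_affine, tolerance = 1e-6)
  # independent read: raw file holds negated x/y components (RAS -> LPS)
  raw <- as.array(RNifti::readNifti(f))
  expect_equal(array(raw[, , , 1, 1], dim(w$displacement)[1:3]),
               -w$displacement[, , , 1])
  expect_equal(array(raw[, , , 1, 3], dim(w$displacement)[1:3]),
               w$displacement[, , , 3])
  # plain 3-volume alternative
  fp <- tempfile(fileext = ".nii.gz")
  write_itk_warp(w, fp, format = "plain")
  backp <- read_itk_warp(fp, "unfolded_to_native", format = "plain")
  expect_identical(backp$displacement, w$displacement)
})

test_that("a zero warp leaves points and images unchanged", {
  spec <- unfolded_space_spec("hipp")
  w0 <- warp_field(array(0, c(8, 8, 4, 3)), "unfolded_to_native",
                   diag(c(1, 1, 1, 1)))
  pts <- cbind(runif(50, 0, 7), runif(50, 0, 7), runif(50, 0, 3))
  expect_equal(transform_points(w0, pts), pts)
  f <- tempfile(fileext = ".nii.gz")
  write_itk_warp(w0, f)
  w0b <- read_itk_warp(f, "unfolded_to_native")
  expect_equal(transform_points(w0b, pts), pts)
  img <- list(data = array(rnorm(8 * 8 * 4), c(8, 8, 4)), affine = diag(4))
  out <- apply_warp(img, w0)
  expect_equal(out$data, img$data, tolerance = 1e-12)
})

test_that("warp application to a mesh matches direct scattered evaluation", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  spec <- unfolded_space_spec("hipp")
  w <- get_warp_u2n()
  ftmp <- tempfile(fileext = ".nii.gz")
  write_itk_warp(w, ftmp)
  w2 <- read_itk_warp(ftmp, "unfolded_to_native")
  # probe at exact unfolded grid nodes: the serialized + trilinear path must
  # agree with the direct scattered-interpolant values there
  set.seed(3)
  nodes <- cbind(sample(0:255, 400, TRUE), sample(0:127, 400, TRUE),
                 sample(0:15, 400, TRUE))
  qs <- voxel_to_world(spec$affine, nodes)
  direct <- qs + t(vapply(seq_len(nrow(nodes)), function(i)
    w$displacement[nodes[i, 1] + 1, nodes[i, 2] + 1, nodes[i, 3] + 1, ],
    numeric(3)))
  via_file <- transform_points(w2, qs)
  expect_lt(max(abs(via_file - direct)), 1e-3)
})

test_that("nearest-neighbour image warping never invents label values", {
  ph <- get_phantom_nocyst()
  w <- get_warp_u2n()
  pulled <- apply_warp(ph$labelmap, w)
  expect_true(all(unique(as.vector(pulled$data)) %in%
                    c(0L, unname(ph$labelmap$label_scheme))))
  expect_identical(dim(pulled$data), w$ref_shape)
})

test_that("rigidly rotated labelmaps give matching unfolded images", {
  ph <- get_phantom_nocyst()
  lm <- ph$labelmap
  dims <- dim(lm$data)
  # rotate 90 degrees about the y axis: new[i,j,k] = old[k, j, nx+1-i]
  rot_data <- aperm(lm$data[, , dim(lm$data)[3]:1], c(3, 2, 1))
  rot <- matrix(c(0, 0, -1, 0,
                  0, 1, 0, 0,
                  1, 0, 0, 0,
                  0, 0, 0, 1), 4, 4, byrow = TRUE)
  idxmap <- matrix(c(0, 0, 1, 0,
                     0, 1, 0, 0,
                     -1, 0, 0, dims[1] - 1,
                     0, 0, 0, 1), 4, 4, byrow = TRUE)
  lm_rot <- tissue_labelmap(rot_data, rot %*% lm$affine %*% idxmap)
  f1 <- get_fields()
  f2 <- compute_coord_fields(lm_rot)
  spec <- unfolded_space_spec("hipp")
  w1 <- build_native_to_unfolded(f1, lm, spec)
  w2 <- build_native_to_unfolded(f2, lm_rot, spec)
  gm_idx <- which(f1$domain_mask, arr.ind = TRUE)
  # homologous voxel in the rotated grid
  gm_rot <- cbind(dims[3] + 1L - gm_idx[, 3], gm_idx[, 2], gm_idx[, 1])
  img1 <- voxel_to_world(lm$affine, gm_idx - 1L) + t(apply(gm_idx, 1, function(v)
    w1$displacement[v[1], v[2], v[3], ]))
  img2 <- voxel_to_world(lm_rot$affine, gm_rot - 1L) + t(apply(gm_rot, 1, function(v)
    w2$displacement[v[1], v[2], v[3], ]))
  err_vox <- sqrt(rowSums((img1 - img2)^2)) / spec$voxel_size
  expect_lt(quantile(err_vox, 0.95), 2)
})

test_that("unfolded AP images are monotone along phantom streamlines", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  truth <- ph$truth
  gm <- f$domain_mask
  # streamline: GM voxels in a narrow generative (pd, depth) tube, ordered
  # by the generative longitudinal parameter and binned
  sel <- gm & abs(truth$true_pd - 0.5) < 0.06 & abs(truth$true_depth - 0.5) < 0.15
  u <- truth$true_ap[sel]
  a <- f$ap[sel]
  bins <- cut(u, seq(0, 1, by = 0.05))
  prof <- tapply(a, bins, mean)
  prof <- prof[!is.na(prof)]
  expect_true(all(diff(prof) > 0))
})

test_that("degenerate scattered inputs raise errors", {
  lm <- tissue_labelmap(array(0L, c(6, 6, 6)), diag(4))
  flat <- array(NaN, c(6, 6, 6))
  dm <- array(FALSE, c(6, 6, 6))
  expect_error(build_native_to_unfolded(
    coord_fields(flat, flat, flat, dm, "laplace"), lm), "empty")
  # coplanar sites: a single-voxel-thick sheet of coordinates
  dm2 <- dm; dm2[2:5, 2:5, 3] <- TRUE
  ap <- flat; pd <- flat; io <- flat
  ap[dm2] <- runif(sum(dm2)); pd[dm2] <- runif(sum(dm2)); io[dm2] <- 0.5
  expect_error(build_unfolded_to_native(
    coord_fields(ap, pd, io, dm2, "laplace"), lm), "coplanar")
})
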