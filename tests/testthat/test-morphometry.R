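# Thickness, mesh smoothing, mean curvature, vertex areas, gyrification and
# volume-to-surface sampling, against analytic oracles.

test_that("thickness is exact for parallel sheets and concentric spheres", {
  inner <- make_plane_mesh(12, 12, spacing = 1)
  outer <- inner
  outer$vertices[, 3] <- 1.2
  th <- thickness(inner, outer)
  expect_equal(th$values, rep(1.2, nrow(inner$vertices)))

  s1 <- make_icosphere(10, 2)
  s2 <- s1
  s2$vertices <- s1$vertices * 1.2  # radial correspondence to r = 12
  th2 <- thickness(s1, s2)
  expect_equal(th2$values, rep(2, nrow(s1$vertices)), tolerance = 1e-6)

  bad <- make_plane_mesh(5, 5)
  expect_error(thickness(inner, bad), "mismatch")
})

test_that("smoothing with strength 0 is the identity and defaults kill a spike", {
  m <- make_plane_mesh(15, 15, spacing = 1)
  expect_identical(smooth_mesh(m, strength = 0), m)
  spike <- m
  centre <- which(spike$vertices[, 1] == 7 & spike$vertices[, 2] == 7)
  spike$vertices[centre, 3] <- 5
  sm <- smooth_mesh(spike)  # defaults: strength 0.6, 100 iterations
  expect_lt(abs(sm$vertices[centre, 3]) / 5, 0.01)
  expect_identical(sm$triangles, spike$triangles)
  # independent averaging oracle, few iterations on the raw definition
  adj <- as.matrix(unfoldcoords:::vertex_adjacency(spike)) > 0
  v <- spike$vertices
  for (it in 1:3) {
    nb_mean <- t(vapply(seq_len(nrow(v)), function(i)
      colMeans(v[adj[i, ], , drop = FALSE]), numeric(3)))
    v <- 0.4 * v + 0.6 * nb_mean
  }
  expect_equal(smooth_mesh(spike, 0.6, 3L)$vertices, v, tolerance = 1e-12)
})

test_that("mean curvature matches plane, sphere and saddle oracles", {
  m <- make_plane_mesh(15, 15, spacing = 1)
  h <- mean_curvature(m)
  int <- interior_vertices(m)
  expect_lt(max(abs(h$values[int])), 1e-6)

  sp <- make_icosphere(5, 3)
  hs <- mean_curvature(sp)
  expect_lt(max(abs(abs(hs$values) - 0.2)) / 0.2, 0.05)
  # all same sign on a sphere
  expect_equal(length(unique(sign(hs$values))), 1L)

  # saddle z = x * y / 4: principal curvatures cancel at the origin
  sd <- make_plane_mesh(21, 21, spacing = 0.25)
  sd$vertices[, 1:2] <- sd$vertices[, 1:2] - 2.5
  sd$vertices[, 3] <- sd$vertices[, 1] * sd$vertices[, 2] / 4
  hsad <- mean_curvature(sd)
  origin <- which(abs(sd$vertices[, 1]) < 1e-9 & abs(sd$vertices[, 2]) < 1e-9)
  expect_lt(abs(hsad$values[origin]), 0.02)
})

test_that("curvature sign flips under mesh mirroring", {
  sp <- make_icosphere(5, 2)
  h1 <- mean_curvature(sp)
  mir <- sp
  mir$vertices[, 1] <- -mir$vertices[, 1]
  h2 <- mean_curvature(mir)
  expect_equal(h2$values, -h1$values, tolerance = 1e-9)
})

test_that("vertex area is the mean of incident triangle areas", {
  m <- make_plane_mesh(10, 10, spacing = 1)
  va <- vertex_area(m)
  int <- interior_vertices(m)
  # interior grid vertex: six incident right triangles of area 0.5
  expect_equal(va$values[int], rep(0.5, length(int)))
  # similarity scaling: x3 scales areas x9 exactly
  m3 <- m
  m3$vertices <- m$vertices * 3
  expect_equal(vertex_area(m3)$values, va$values * 9)
  # brute-force oracle on a jittered (still planar) triangulation
  set.seed(42)
  j <- m
  j$vertices[, 1:2] <- j$vertices[, 1:2] + matrix(runif(200, -0.2, 0.2), 100)
  areas <- unfoldcoords:::triangle_normals(j)$areas
  oracle <- vapply(seq_len(nrow(j$vertices)), function(v) {
    inc <- which(rowSums(j$triangles == v) > 0)
    if (!length(inc)) 0 else mean(areas[inc])
  }, numeric(1))
  expect_equal(vertex_area(j)$values, oracle, tolerance = 1e-12)
})

test_that("gyrification is the vertex area ratio with exact scaling", {
  m <- make_plane_mesh(12, 12, spacing = 1)
  expect_equal(gyrification(m, m)$values, rep(1, nrow(m$vertices)))
  m3 <- m
  m3$vertices <- m$vertices * 3
  expect_equal(gyrification(m3, m)$values, rep(9, nrow(m$vertices)),
               tolerance = 1e-9)
})

test_that("phantom gyrification integrates to the analytic area ratio", {
  res <- get_default_pipeline()
  layers <- res$surfaces$unfoldiso
  gy <- gyrification(layers$midthickness, layers$unfolded_midthickness)
  a_nat <- vertex_area(layers$midthickness)$values
  a_unf <- vertex_area(layers$unfolded_midthickness)$values
  global <- sum(a_nat) / sum(a_unf)
  spec <- unfolded_space_spec("hipp")
  truth <- phantom_native_area(phantom_params()) /
    (spec$extent[1] * spec$extent[2])
  expect_lt(abs(global - truth) / truth, 0.02)
  expect_true(all(gy$values > 0))
})

test_that("metrics are invariant under vertex renumbering", {
  m <- make_plane_mesh(8, 8, spacing = 1)
  set.seed(5)
  perm <- sample(nrow(m$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mp <- m
  mp$vertices <- m$vertices[perm, ]
  mp$triangles <- matrix(inv[m$triangles], ncol = 3)
  expect_equal(vertex_area(mp)$values[inv], vertex_area(m)$values)
  expect_equal(mean_curvature(mp)$values[inv], mean_curvature(m)$values,
               tolerance = 1e-9)
})

test_that("volume sampling reproduces constants and linear ramps", {
  dims <- c(20L, 20L, 20L)
  aff <- diag(c(0.5, 0.5, 0.5, 1)); aff[1:3, 4] <- c(-4, -4, -4)
  m <- make_plane_mesh(9, 9, spacing = 0.4)
  m$vertices <- sweep(m$vertices, 2, c(-1.5, -1.5, 0.7), "+")
  const <- list(data = array(3.25, dims), affine = aff)
  expect_equal(sample_to_surface(const, m)$values,
               rep(3.25, nrow(m$vertices)))
  ijk <- voxel_grid(dims)
  ramp <- list(data = array(voxel_to_world(aff, ijk)[, 1], dims), affine = aff)
  got <- sample_to_surface(ramp, m)
  expect_equal(got$values, m$vertices[, 1], tolerance = 1e-9)
  # out-of-bounds vertices are NaN with a count
  mfar <- m
  mfar$vertices[1, ] <- c(100, 100, 100)
  far <- sample_to_surface(ramp, mfar)
  expect_true(is.nan(far$values[1]))
  expect_identical(attr(far, "n_outside"), 1L)
})

test_that("a myelin-like phantom image samples brighter on the inner surface", {
  ph <- get_phantom_nocyst()
  qi <- phantom_quantitative_image(ph$labelmap, ph$truth)
  layers <- get_layers_iso()
  v_in <- sample_to_surface(qi, layers$inner)$values
  v_mid <- sample_to_surface(qi, layers$midthickness)$values
  ok <- is.finite(v_in) & is.finite(v_mid)
  expect_gt(mean(v_in[ok]), mean(v_mid[ok]))
})
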