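# Laplace solver, geodesic initialization and the equivolumetric transform.

slab_setup <- function(n = 20L, w = 10L) {
  dims <- c(n + 4L, w + 2L, w + 2L)
  dom <- array(FALSE, dims); dom[3:(n + 2), 2:(w + 1), 2:(w + 1)] <- TRUE
  src <- array(FALSE, dims); src[2, 2:(w + 1), 2:(w + 1)] <- TRUE
  snk <- array(FALSE, dims); snk[n + 3, 2:(w + 1), 2:(w + 1)] <- TRUE
  list(dom = dom, src = src, snk = snk, n = n)
}

test_that("slab solution matches the 1D linear closed form", {
  s <- slab_setup()
  f <- solve_laplace(s$dom, s$src, s$snk, tol = 1e-8)
  prof <- f[3:(s$n + 2), 6, 6]
  expect_lt(max(abs(prof - (seq_len(s$n) - 0.5) / s$n)), 1e-3)
  # whole interior, not just one line
  vals <- f[s$dom]
  expect_true(all(vals > 0 & vals < 1))  # discrete maximum principle
})

test_that("L-shaped domain agrees with an independent dense Jacobi oracle", {
  dims <- c(14L, 14L, 5L)
  dom <- array(FALSE, dims)
  dom[3:12, 3:5, 2:4] <- TRUE   # horizontal arm
  dom[3:5, 3:12, 2:4] <- TRUE   # vertical arm
  src <- array(FALSE, dims); src[2, 3:5, 2:4] <- TRUE
  snk <- array(FALSE, dims); snk[3:5, 13, 2:4] <- TRUE
  f <- solve_laplace(dom, src, snk, tol = 1e-10, max_iter = 50000L)
  oracle <- jacobi_oracle(dom, src, snk, tol = 1e-12, max_iter = 1e5)
  expect_lt(max(abs(f[dom] - oracle[dom])), 1e-6)
})

test_that("solver errors when an endpoint does not touch the domain", {
  s <- slab_setup(8L, 4L)
  far <- array(FALSE, dim(s$dom)); far[1, 1, 1] <- TRUE
  expect_error(solve_laplace(s$dom, far, s$snk), "not connected")
})

test_that("geodesic initialization is monotone on a bar and path-based on a U", {
  dims <- c(24L, 5L, 5L)
  dom <- array(FALSE, dims); dom[3:22, 3, 3] <- TRUE
  src <- array(FALSE, dims); src[2, 3, 3] <- TRUE
  snk <- array(FALSE, dims); snk[23, 3, 3] <- TRUE
  init <- init_field_geodesic(dom, src, snk)
  bar <- init[3:22, 3, 3]
  expect_true(all(diff(bar) > 0))
  expect_equal(bar, (1:20) / 21, tolerance = 1e-12)

  # U-shaped corridor: initialization follows path length, not Euclidean
  dimsu <- c(12L, 12L, 3L)
  domu <- array(FALSE, dimsu)
  domu[2:10, 2, 2] <- TRUE; domu[10, 2:10, 2] <- TRUE; domu[2:10, 10, 2] <- TRUE
  srcu <- array(FALSE, dimsu); srcu[1, 2, 2] <- TRUE
  snku <- array(FALSE, dimsu); snku[1, 10, 2] <- TRUE
  initu <- init_field_geodesic(domu, srcu, snku)
  # start of the first arm: path distance 1 of 25 steps; its Euclidean
  # distance to the sink arm is small but the along-path value must be low
  expect_equal(initu[2, 2, 2], 1 / 26, tolerance = 1e-12)
  expect_equal(initu[2, 10, 2], 25 / 26, tolerance = 1e-12)
  expect_equal(initu[10, 6, 2], 0.5, tolerance = 1e-12)  # mid-path

  # isolated island voxel gets 0.5 with a warning
  domi <- domu; domi[5, 5, 2] <- TRUE
  expect_warning(initi <- init_field_geodesic(domi, srcu, snku), "unreachable")
  expect_equal(initi[5, 5, 2], 0.5)
})

test_that("solution is initialization-invariant and equivariant to source/sink swap", {
  s <- slab_setup(10L, 6L)
  dims <- dim(s$dom)
  tol <- 1e-7
  f_geo <- solve_laplace(s$dom, s$src, s$snk, tol = tol)
  f_const <- solve_laplace(s$dom, s$src, s$snk, tol = tol,
                           init = array(0.5, dims))
  expect_lt(max(abs(f_geo[s$dom] - f_const[s$dom])), 10 * tol)
  f_swap <- solve_laplace(s$dom, s$snk, s$src, tol = tol)
  expect_lt(max(abs((1 - f_swap[s$dom]) - f_geo[s$dom])), 1e-6)
})

test_that("connectivity 18 and 26 stencils are accepted and stay in range", {
  s <- slab_setup(8L, 4L)
  for (conn in c(18L, 26L)) {
    f <- solve_laplace(s$dom, s$src, s$snk, tol = 1e-6, connectivity = conn)
    expect_true(all(f[s$dom] > 0 & f[s$dom] < 1))
  }
})

test_that("equivolume transform matches the analytic annulus and its limits", {
  # annulus with inner perimeter 1, outer 2: the equal-volume radius for
  # volume fraction 1/3 is sqrt(1 + 3 * 1/3) = sqrt(2), depth sqrt(2) - 1
  expect_equal(equivolume_transform(1 / 3, 1, 2), sqrt(2) - 1,
               tolerance = 1e-9)
  # numeric-integration oracle: invert the cumulative area fraction of an
  # annulus r in [1, 2]
  r <- seq(1, 2, length.out = 20001)
  cumfrac <- (r^2 - 1) / 3
  rho_num <- approx(cumfrac, (r - 1), xout = 1 / 3)$y
  expect_equal(equivolume_transform(1 / 3, 1, 2), rho_num, tolerance = 1e-6)
  # flat-sheet limit and boundary preservation
  a <- seq(0, 1, by = 0.05)
  expect_equal(equivolume_transform(a, 2.5, 2.5), a)
  expect_equal(equivolume_transform(c(0, 1), 1.3, 3.7), c(0, 1))
  expect_error(equivolume_transform(0.5, -1, 2), "positive")
})

test_that("equivolume transform is a monotone bijection of [0,1]", {
  a <- seq(0, 1, length.out = 101)
  for (areas in list(c(1, 2), c(3, 0.5), c(0.2, 0.2001))) {
    rho <- equivolume_transform(a, areas[1], areas[2])
    expect_true(all(diff(rho) > 0))
    expect_true(all(rho >= 0 & rho <= 1))
    back <- unfoldcoords:::equivolume_inverse(rho, areas[1], areas[2])
    expect_equal(back, a, tolerance = 1e-10)
  }
})

test_that("phantom coordinate fields span their axes and are non-degenerate", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  gm <- f$domain_mask
  # AP minimum sits against HATA, maximum against IndGris
  hata_adj <- unfoldcoords:::label_mask(ph$labelmap, "HATA")
  expect_lt(min(f$ap[gm]), 0.02)
  expect_gt(max(f$ap[gm]), 0.98)
  expect_true(all(f$ap[gm] >= 0 & f$ap[gm] <= 1))
  lowest <- which(f$ap == min(f$ap[gm]), arr.ind = TRUE)[1, ]
  nb <- ph$labelmap$data[lowest[1] + (-2:2), lowest[2] + (-2:2), lowest[3] + (-2:2)]
  expect_true(any(nb == ph$labelmap$label_scheme["HATA"]))

  # io_mode = "laplace" bypasses the equivolumetric replacement
  f_lap <- compute_coord_fields(ph$labelmap, io_mode = "laplace")
  expect_identical(f_lap$io_mode, "laplace")
  expect_false(isTRUE(all.equal(f$io[gm], f_lap$io[gm])))

  # slab phantom: the three fields are mutually non-degenerate
  slab <- memo("slab_phantom", generate_phantom(
    small_params(0L, curl_turns = 0, n_digitations = 0L,
                 digitation_amplitude = 0)))
  fs <- memo("slab_fields", compute_coord_fields(slab$labelmap))
  g <- fs$domain_mask
  combos <- list(c("ap", "pd"), c("ap", "io"), c("pd", "io"))
  for (cb in combos)
    expect_lt(abs(cor(fs[[cb[1]]][g], fs[[cb[2]]][g], method = "spearman")),
              0.5)
})

test_that("coordinate fields are NaN outside the domain and written as NIfTI", {
  ph <- get_phantom_nocyst()
  f <- get_fields()
  expect_true(all(is.nan(f$ap[!f$domain_mask])))
  expect_true(all(is.finite(f$ap[f$domain_mask])))
  pre <- tempfile()
  paths <- write_coord_fields(f, ph$labelmap, pre)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[1])
  expect_equal(dim(back), dim(ph$labelmap$data))
})
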