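# Shared fixtures, memoized across test files (testthat runs all files in
# one session; the cache lives in options so helpers re-sourced per file do
# not recompute).

uc_cache <- function() {
  env <- getOption("unfoldcoords.test.cache")
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    options(unfoldcoords.test.cache = env)
  }
  env
}

memo <- function(key, expr) {
  env <- uc_cache()
  if (!exists(key, envir = env)) assign(key, expr, envir = env)
  get(key, envir = env)
}

# component-scale phantom: same topology as the default, smaller grid
small_params <- function(n_cysts = 1L, ...) {
  args <- list(length = 16, width = 9, thickness = 1.2, curl_turns = 0.4,
               n_digitations = 2L, digitation_amplitude = 0.6,
               grid_shape = c(64L, 96L, 64L), n_cysts = n_cysts, seed = 7L)
  do.call(phantom_params, utils::modifyList(args, list(...)))
}

get_phantom <- function() memo("phantom", generate_phantom(small_params()))
get_phantom_nocyst <- function()
  memo("phantom0", generate_phantom(small_params(0L)))
get_template <- function() memo("template", generate_template(small_params(0L)))

get_fields <- function()
  memo("fields", compute_coord_fields(get_phantom_nocyst()$labelmap))

get_warp_u2n <- function()
  memo("warp_u2n", build_unfolded_to_native(get_fields(),
                                            get_phantom_nocyst()$labelmap))
get_warp_n2u <- function()
  memo("warp_n2u", build_native_to_unfolded(get_fields(),
                                            get_phantom_nocyst()$labelmap))

get_layers_iso <- function()
  memo("layers_iso", build_layer_surfaces(unfolded_space_spec("hipp"),
                                          get_warp_u2n(), "unfoldiso"))

get_inject_digitated <- function()
  memo("inject_digitated", inject(get_template(), get_phantom_nocyst()$labelmap))

# full-scale default phantom and its pipeline run (used by the end-to-end
# parameter-recovery checks)
get_default_phantom <- function()
  memo("default_phantom", generate_phantom(phantom_params()))
get_default_pipeline <- function()
  memo("default_pipeline", {
    ph <- get_default_phantom()
    run_pipeline(ph$labelmap, file.path(tempdir(), "uc_default_pipe"),
                 pipeline_config(densities = c("0p5mm", "unfoldiso")))
  })

# a flat axis-aligned slab labelmap with GM a rectangular prism and linear
# analytic coordinate fields (for closed-form warp checks)
make_affine_prism <- function(dims = c(24L, 40L, 16L), vs = 0.5) {
  data <- array(0L, dims)
  gm <- list(x = 5:20, y = 6:35, z = 5:12)
  data[gm$x, gm$y, gm$z] <- 1L
  affine <- diag(c(vs, vs, vs, 1)); affine[1:3, 4] <- c(-3, -7, -2)
  lm <- tissue_labelmap(data, affine)
  lin <- function(idx, rng) (idx - min(rng)) / (max(rng) - min(rng))
  ap <- array(NaN, dims); pd <- ap; io <- ap
  ix <- slice.index(data, 1); iy <- slice.index(data, 2); iz <- slice.index(data, 3)
  sel <- data == 1L
  ap[sel] <- lin(iy[sel], gm$y)
  pd[sel] <- lin(ix[sel], gm$x)
  io[sel] <- lin(iz[sel], gm$z)
  list(lm = lm, fields = coord_fields(ap, pd, io, data == 1L, "laplace"),
       gm = gm)
}

# icosphere built by subdividing an icosahedron, outward winding
make_icosphere <- function(radius = 5, subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!exists(key, edge_mid)) {
        m <- v[a, ] + v[b, ]
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        assign(key, nrow(v), edge_mid)
      }
      get(key, edge_mid)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  surface_mesh(v * radius, f, space = "native", structure = "hipp")
}

# flat triangulated plane in the z = 0 plane with given spacing
make_plane_mesh <- function(nx = 20L, ny = 20L, spacing = 1) {
  x <- rep(seq_len(nx) - 1, times = ny) * spacing
  y <- rep(seq_len(ny) - 1, each = nx) * spacing
  verts <- cbind(x, y, 0)
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (j - 1L) * nx + i; v10 <- v00 + 1L; v01 <- v00 + nx; v11 <- v01 + 1L
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface_mesh(verts, tris, space = "native", structure = "hipp",
               unfolded_coords = cbind(x / max(x), y / max(y)))
}

# interior vertex selector for a plane/grid mesh (all 6 neighbors present)
interior_vertices <- function(mesh) {
  e <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
             mesh$triangles[, c(3, 1)])
  deg <- tabulate(e, nbins = nrow(mesh$vertices))
  which(deg >= 12)  # each interior vertex appears in 6 triangles x 2 edges
}

get_pipe_small <- function()
  memo("pipe_small", {
    cfg <- pipeline_config(densities = c("2mm", "unfoldiso"),
                           template = get_template())
    run_pipeline(get_phantom_nocyst()$labelmap,
                 file.path(tempdir(), "uc_pipe1"), cfg)
  })
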