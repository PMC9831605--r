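# Oracles shared across test files.

# independent dense Jacobi relaxation oracle on the same stencil (Dirichlet
# values at boundary-voxel faces, i.e. weight-2 neighbors)
jacobi_oracle <- function(domain, src, snk, tol = 1e-10, max_iter = 2e5) {
  dims <- dim(domain)
  shift <- function(a, dx, dy, dz) {
    out <- array(NA_real_, dims)
    sx <- seq_len(dims[1]); sy <- seq_len(dims[2]); sz <- seq_len(dims[3])
    out[intersect(sx, sx - dx), intersect(sy, sy - dy), intersect(sz, sz - dz)] <-
      a[intersect(sx, sx + dx), intersect(sy, sy + dy), intersect(sz, sz + dz)]
    out
  }
  val <- array(NA_real_, dims)
  val[domain] <- 0.5; val[src] <- 0; val[snk] <- 1
  wt <- array(0, dims)
  wt[domain] <- 1; wt[src] <- 2; wt[snk] <- 2
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (it in seq_len(max_iter)) {
    num <- array(0, dims); den <- array(0, dims)
    for (o in seq_len(6)) {
      vs <- shift(val, offs[o, 1], offs[o, 2], offs[o, 3])
      ws <- shift(wt, offs[o, 1], offs[o, 2], offs[o, 3])
      ws[is.na(ws) | is.na(vs)] <- 0
      vs[is.na(vs)] <- 0
      num <- num + ws * vs; den <- den + ws
    }
    new <- val
    upd <- domain & den > 0
    new[upd] <- (num / pmax(den, 1))[upd]
    delta <- max(abs(new[domain] - val[domain]))
    val <- new
    if (delta < tol) break
  }
  val[!domain] <- NaN
  val
}


sinusoid_target <- function() {
  memo("sinusoid_target", {
    tpl <- get_template()
    tlm <- tpl$labelmap
    dims <- dim(tlm$data)
    g <- unfoldcoords:::voxel_grid(dims)
    amp <- 2 * 0.3  # two voxels
    def <- cbind(0 * g[, 1], 0 * g[, 1],
                 amp * sin(2 * pi * g[, 2] * 0.3 / 24))
    vox2 <- world_to_voxel(tlm$affine, voxel_to_world(tlm$affine, g) + def)
    lab <- unfoldcoords:::cpp_nearest_sample(as.numeric(tlm$data), dims, vox2)
    lab[is.na(lab)] <- 0
    tissue_labelmap(array(as.integer(lab), dims), tlm$affine)
  })
}

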