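# Template shape injection: fluid multi-channel registration of an idealized
# reference labelmap to the subject labelmap, driven by mean squared error on
# smoothed one-hot label channels.  The deformation carries the template's
# precomputed DG coordinate fields into subject space.

#' Template shape container
#'
#' @param labelmap idealized reference [tissue_labelmap()]
#' @param dg_fields [coord_fields()] precomputed on the template's DG voxels
#' @param metadata free-form list
#' @return object of class `template_shape`
#' @export
template_shape <- function(labelmap, dg_fields, metadata = list()) {
  structure(list(labelmap = labelmap, dg_fields = dg_fields,
                 metadata = metadata), class = "template_shape")
}

#' Smoothed one-hot label channels
#'
#' One channel per label value present in the scheme (background included),
#' each the Gaussian-smoothed binary mask.  Linear smoothing preserves the
#' partition of unity: the channels sum to 1 everywhere (up to border
#' truncation of the kernel).
#'
#' @param lm a [tissue_labelmap()]
#' @param sigma smoothing in mm (0 gives the exact one-hot encoding)
#' @return list with `data` (4D array, last dim = channel), `labels`,
#'   `affine`, `voxel_size`
#' @export
smooth_onehot <- function(lm, sigma = 1) {
  stopifnot(sigma >= 0)
  dims <- dim(lm$data)
  labels <- sort(unique(c(0L, lm$label_scheme[lm$label_scheme %in% lm$data])))
  ch <- array(0, c(dims, length(labels)))
  sig_vox <- sigma / lm$voxel_size
  for (i in seq_along(labels)) {
    m <- as.numeric(lm$data == labels[i])
    if (sigma > 0) m <- cpp_gaussian_smooth(m, dims, sig_vox)
    ch[, , , i] <- m
  }
  list(data = ch, labels = labels, affine = lm$affine,
       voxel_size = lm$voxel_size)
}

# block-resample channels to a coarser grid by factor f (integer)
coarsen_channels <- function(ch, f) {
  if (f == 1L) return(ch)
  dims <- dim(ch$data)[1:3]
  nd <- pmax(2L, as.integer(floor((dims - 1) / f) + 1L))
  g <- voxel_grid(nd) * f
  nc <- dim(ch$data)[4]
  out <- array(0, c(nd, nc))
  for (c in seq_len(nc)) {
    sm <- cpp_gaussian_smooth(as.vector(ch$data[, , , c]), dims, rep(f / 2, 3))
    out[, , , c] <- cpp_trilinear(sm, dims, g)
  }
  aff <- ch$affine %*% diag(c(f, f, f, 1))
  list(data = out, labels = ch$labels, affine = aff,
       voxel_size = ch$voxel_size * f)
}

# pull channels through a displacement field defined on their own grid;
# sampling is clamped at the grid border (edge extension) so displacements
# near the crop boundary do not spuriously change the cost
pull_channels <- function(ch, disp) {
  dims <- dim(ch$data)[1:3]
  world <- voxel_to_world(ch$affine, voxel_grid(dims)) + matrix(disp, ncol = 3)
  vox <- world_to_voxel(ch$affine, world)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), dims[a] - 1)
  nc <- dim(ch$data)[4]
  out <- array(0, c(dims, nc))
  for (c in seq_len(nc))
    out[, , , c] <- cpp_trilinear(as.vector(ch$data[, , , c]), dims, vox)
  out
}

# central-difference spatial gradient of a 3D array, per mm
grad3 <- function(a, voxel_size) {
  d <- dim(a)
  gx <- a; gy <- a; gz <- a
  gx[] <- 0; gy[] <- 0; gz[] <- 0
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / (2 * voxel_size[1])
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / (2 * voxel_size[2])
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) / (2 * voxel_size[3])
  list(gx, gy, gz)
}

#' Multi-channel demons-style label registration
#'
#' Minimizes the summed per-channel mean squared error between the warped
#' template channels and the target channels by multi-resolution gradient
#' descent with Gaussian regularization of both the update and the total
#' displacement field ("fluid" registration).  The step size adapts so the
#' cost trace is non-increasing within each level.
#'
#' @param template_ch,target_ch channel sets from [smooth_onehot()], on the
#'   same world grid
#' @param levels coarsening factors, finest last (e.g. `c(4, 2, 1)`)
#' @param iters iterations per level
#' @param step maximum displacement per iteration, in voxels of the level
#' @param smooth_update Gaussian sigma (mm) applied to each update
#' @param smooth_total Gaussian sigma (mm) applied to the accumulated field
#' @return object of class `deformation`: `displacement` (4D mm, on the
#'   target grid), `cost_trace` (list per level), `ref_affine`
#' @export
register_labels <- function(template_ch, target_ch, levels = c(4L, 2L, 1L),
                            iters = 150L, step = 0.8,
                            smooth_update = 1.5, smooth_total = 0.2) {
  if (!isTRUE(all.equal(template_ch$affine, target_ch$affine)))
    stop("template and target channel grids differ")
  disp <- NULL
  traces <- list()
  for (li in seq_along(levels)) {
    f <- as.integer(levels[li])
    tpl <- coarsen_channels(template_ch, f)
    tgt <- coarsen_channels(target_ch, f)
    dims <- dim(tpl$data)[1:3]
    nvox <- prod(dims); nc <- dim(tpl$data)[4]
    if (is.null(disp)) {
      disp <- matrix(0, nvox, 3)
    } else {
      # upsample the previous level's field onto this grid
      w <- voxel_to_world(tpl$affine, voxel_grid(dims))
      vox_prev <- world_to_voxel(prev_affine, w)
      for (a in 1:3) vox_prev[, a] <- pmin(pmax(vox_prev[, a], 0), prev_dims[a] - 1)
      disp <- vapply(1:3, function(c)
        cpp_trilinear(prev_disp[, c], prev_dims, vox_prev), numeric(nvox))
    }
    sig_up <- smooth_update / tpl$voxel_size
    sig_tot <- smooth_total / tpl$voxel_size
    step_mm <- step * mean(tpl$voxel_size)
    cost_of <- function(d) {
      warped <- pull_channels(tpl, d)
      sum((warped - tgt$data)^2) / nvox
    }
    trace <- numeric(0)
    cost <- cost_of(disp)
    trace <- c(trace, cost)
    kappa2 <- mean(tpl$voxel_size)^2
    tgt_grads <- lapply(seq_len(nc), function(c)
      lapply(grad3(tgt$data[, , , c], tgt$voxel_size), as.vector))
    tau <- 1
    for (it in seq_len(iters)) {
      warped <- pull_channels(tpl, array(disp, c(dims, 3)))
      diffs <- warped - tgt$data
      # symmetric demons force: per-voxel normalized steepest descent with
      # the efficient second-order gradient (mean of warped-template and
      # target gradients), summed over channels; step magnitude is naturally
      # bounded by ~ half a voxel
      force <- matrix(0, nvox, 3)
      for (c in seq_len(nc)) {
        gw <- grad3(warped[, , , c], tpl$voxel_size)
        gt <- tgt_grads[[c]]
        g1 <- 0.5 * (as.vector(gw[[1]]) + gt[[1]])
        g2 <- 0.5 * (as.vector(gw[[2]]) + gt[[2]])
        g3 <- 0.5 * (as.vector(gw[[3]]) + gt[[3]])
        dc <- as.vector(diffs[, , , c])
        denom <- g1^2 + g2^2 + g3^2 + dc^2 / kappa2
        w <- ifelse(denom > 1e-12, dc / denom, 0)
        force[, 1] <- force[, 1] - w * g1
        force[, 2] <- force[, 2] - w * g2
        force[, 3] <- force[, 3] - w * g3
      }
      if (!all(is.finite(force))) stop("non-finite registration cost gradient")
      for (a in 1:3) force[, a] <- cpp_gaussian_smooth(force[, a], dims, sig_up)
      if (max(abs(force)) < 1e-12) break
      accepted <- FALSE
      while (tau >= 1e-3) {
        cand <- disp + (tau * step_mm / mean(tpl$voxel_size)) * force
        for (a in 1:3) cand[, a] <- cpp_gaussian_smooth(cand[, a], dims, sig_tot)
        cand_cost <- cost_of(array(cand, c(dims, 3)))
        if (cand_cost <= cost * (1 + 1e-9)) {
          disp <- cand; cost <- cand_cost; accepted <- TRUE
          tau <- min(tau * 1.2, 1)
          break
        }
        tau <- tau / 2
      }
      if (!accepted) break
      trace <- c(trace, cost)
    }
    traces[[li]] <- trace
    prev_disp <- disp; prev_dims <- dims; prev_affine <- tpl$affine
  }
  structure(list(displacement = array(prev_disp, c(prev_dims, 3)),
                 cost_trace = traces, ref_affine = prev_affine,
                 params = list(levels = levels, iters = iters, step = step,
                               smooth_update = smooth_update,
                               smooth_total = smooth_total)),
            class = "deformation")
}

#' @export
print.deformation <- function(x, ...) {
  costs <- vapply(x$cost_trace, function(t) t[length(t)], numeric(1))
  cat("<deformation> grid ", paste(dim(x$displacement)[1:3], collapse = " x "),
      ", final costs per level: ", paste(signif(costs, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of `I + du/dx` by central differences; values > 0 indicate an
#' orientation-preserving (locally invertible) map.
#'
#' @param def a `deformation` from [register_labels()]
#' @return 3D array of determinants on the deformation grid
#' @export
jacobian_determinant <- function(def) {
  dims <- dim(def$displacement)[1:3]
  vs <- sqrt(colSums(def$ref_affine[1:3, 1:3]^2))
  J <- vector("list", 9)
  for (c in 1:3) {
    g <- grad3(def$displacement[, , , c], vs)
    for (a in 1:3) J[[(c - 1) * 3 + a]] <- g[[a]]
  }
  # det(I + J), J[c][a] = d u_c / d x_a
  j11 <- 1 + J[[1]]; j12 <- J[[2]]; j13 <- J[[3]]
  j21 <- J[[4]]; j22 <- 1 + J[[5]]; j23 <- J[[6]]
  j31 <- J[[7]]; j32 <- J[[8]]; j33 <- 1 + J[[9]]
  array(j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
          j13 * (j21 * j32 - j22 * j31), dims)
}

# bounding box (0-based index ranges) of nonzero labels, grown by margin
label_bbox <- function(data, margin, dims) {
  idx <- which(data != 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L - margin, 0L)
  hi <- pmin(apply(idx, 2, max) - 1L + margin, dims - 1L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_labelmap <- function(lm, lo, hi) {
  data <- lm$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                  (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  aff <- lm$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% lo
  tissue_labelmap(data, aff, lm$label_scheme, lm$hemisphere)
}

#' Inject a template shape into a subject segmentation
#'
#' Registers the template labelmap to the subject labelmap (fluid demons on
#' smoothed one-hot channels, label MSE cost), then replaces the subject
#' segmentation by the template labels resampled (nearest) through the
#' deformation, and carries the template's precomputed DG coordinate fields
#' (linear resampling) into subject space.  Registration runs on a cropped
#' region around the labels for efficiency; the returned labelmap is on the
#' full subject grid.
#'
#' @param template a [template_shape()]
#' @param subject the subject [tissue_labelmap()] (same world space)
#' @param sigma label-smoothing sigma in mm for the registration channels
#' @param levels,iters,step,smooth_update,smooth_total see [register_labels()]
#' @param margin crop margin in voxels around the union of labels
#' @return list with `labelmap` (corrected segmentation), `dg_fields`
#'   (subject-space DG [coord_fields()]), and `deformation`
#' @export
inject <- function(template, subject, sigma = 0.3,
                   levels = c(4L, 2L, 1L), iters = 150L, step = 0.8,
                   smooth_update = 1.5, smooth_total = 0.2, margin = 8L) {
  tlm <- template$labelmap
  dims <- dim(subject$data)
  bb_s <- label_bbox(subject$data, margin, dims)
  bb_t <- label_bbox(tlm$data, margin, dim(tlm$data))
  lo <- pmin(bb_s$lo, bb_t$lo); hi <- pmax(bb_s$hi, bb_t$hi)
  sub_c <- crop_labelmap(subject, lo, hi)
  tpl_c <- crop_labelmap(tlm, lo, hi)
  def <- register_labels(smooth_onehot(tpl_c, sigma),
                         smooth_onehot(sub_c, sigma),
                         levels = levels, iters = iters, step = step,
                         smooth_update = smooth_update,
                         smooth_total = smooth_total)
  # evaluate the deformation on the full subject grid (zero far from labels)
  world <- voxel_to_world(subject$affine, voxel_grid(dims))
  dvox <- world_to_voxel(def$ref_affine, world)
  ddims <- dim(def$displacement)[1:3]
  inside <- dvox[, 1] >= 0 & dvox[, 2] >= 0 & dvox[, 3] >= 0 &
    dvox[, 1] <= ddims[1] - 1 & dvox[, 2] <= ddims[2] - 1 &
    dvox[, 3] <= ddims[3] - 1
  disp <- matrix(0, prod(dims), 3)
  for (a in 1:3) {
    v <- cpp_trilinear(as.vector(def$displacement[, , , a]), ddims, dvox)
    disp[inside, a] <- v[inside]
  }
  pulled <- world + disp
  tvox <- world_to_voxel(tlm$affine, pulled)
  lab <- cpp_nearest_sample(as.numeric(tlm$data), dim(tlm$data), tvox)
  lab[is.na(lab)] <- 0
  corrected <- tissue_labelmap(array(as.integer(round(lab)), dims),
                               subject$affine, subject$label_scheme,
                               subject$hemisphere)
  # resample template DG fields (linear) into subject space
  dg_mask <- label_mask(corrected, "DGgranule")
  dgv <- as.vector(dg_mask)
  mk <- function(tmpl_field) {
    src <- tmpl_field
    srcv <- as.vector(src)
    known <- is.finite(srcv)
    filled <- cpp_nearest_fill(matrix(ifelse(known, srcv, 0), ncol = 1),
                               known, dim(src))[, 1]
    v <- cpp_trilinear(filled, dim(src), tvox[dgv, , drop = FALSE])
    out <- rep(NaN, prod(dims))
    out[dgv] <- pmin(pmax(v, 0), 1)
    array(out, dims)
  }
  dg_fields <- coord_fields(mk(template$dg_fields$ap),
                            mk(template$dg_fields$pd),
                            mk(template$dg_fields$io),
                            dg_mask, io_mode = "laplace")
  list(labelmap = corrected, dg_fields = dg_fields, deformation = def)
}
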