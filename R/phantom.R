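# Parametric folded-sheet phantom: a curled, optionally digitated cortical
# ribbon with the full hippocampal tissue-label inventory, rasterized into
# the cropped-space grid, with analytic ground-truth coordinates.
#
# The sheet is parameterized by (u, v, w): u runs along the long (AP) axis,
# v along the curl (PD) arc, w across the laminar thickness.  Tissue bands
# occupy fixed parameter ranges:
#   u: HATA [0.02,0.08) | GM [0.08,0.92] | IndGris (0.92,0.98]
#   v: MTLc [0.02,0.10) | GM [0.10,0.82] | DG granule (0.82,0.90]
#   w: SRLM [-0.35,0)   | GM [0,1]       | pial (1,1.35]
# so the ground-truth coordinates on GM are the normalized (u, v, w).

.p_u <- c(cap0 = 0.02, gm0 = 0.08, gm1 = 0.92, cap1 = 0.98)
.p_v <- c(edge0 = 0.02, gm0 = 0.10, gm1 = 0.82, dg1 = 0.90)
.p_w <- c(srlm = -0.35, pial = 1.35)

#' Phantom parameters
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a half-turn curled sheet with three digitations at anatomically
#' plausible scale (the archicortical ribbon is 0.5-2 mm thick), rasterized
#' into the 128 x 256 x 128 cropped grid at 0.3 mm isotropic.
#'
#' @param curl_turns how far the sheet curls around its axis (0 = flat slab)
#' @param n_digitations number of sinusoidal digitations along AP
#' @param digitation_amplitude digitation displacement amplitude, mm
#' @param thickness laminar thickness, mm (must lie in `[0.5, 2]`)
#' @param length full sheet extent along AP, mm
#' @param width full sheet arc length along PD, mm
#' @param voxel_size isotropic voxel size, mm
#' @param grid_shape output grid dimensions
#' @param n_cysts number of small cyst inclusions placed inside GM
#' @param cyst_radius cyst radius, mm
#' @param seed RNG seed (cyst placement); the rest is deterministic
#' @param hemisphere `"L"` or `"R"`
#' @return object of class `phantom_params`
#' @export
phantom_params <- function(curl_turns = 0.5, n_digitations = 3L,
                           digitation_amplitude = 1, thickness = 1.2,
                           length = 32, width = 16, voxel_size = 0.3,
                           grid_shape = c(128L, 256L, 128L),
                           n_cysts = 1L, cyst_radius = 0.8,
                           seed = 1L, hemisphere = "R") {
  if (thickness < 0.5 || thickness > 2)
    stop("thickness must lie in [0.5, 2] mm")
  if (length <= 0 || width <= 0 || voxel_size <= 0) stop("extents must be positive")
  structure(list(curl_turns = curl_turns, n_digitations = as.integer(n_digitations),
                 digitation_amplitude = digitation_amplitude,
                 thickness = thickness, length = length, width = width,
                 voxel_size = voxel_size, grid_shape = as.integer(grid_shape),
                 n_cysts = as.integer(n_cysts), cyst_radius = cyst_radius,
                 seed = as.integer(seed), hemisphere = hemisphere),
            class = "phantom_params")
}

# world position of sheet samples; u, v, w are equal-length vectors
phantom_surface <- function(p, u, v, w) {
  y <- (u - 0.5) * p$length
  dig <- p$digitation_amplitude * sin(2 * pi * p$n_digitations * u) * sin(pi * v)
  if (p$curl_turns > 1e-3) {
    r0 <- p$width / (2 * pi * p$curl_turns)
    phi <- pi / 2 + 2 * pi * p$curl_turns * (v - 0.5)
    rad <- r0 + dig + (w - 0.5) * p$thickness
    cbind(rad * cos(phi), y, rad * sin(phi) - r0 / 2)
  } else {
    cbind((v - 0.5) * p$width, y, dig + (w - 0.5) * p$thickness)
  }
}

# tissue label for parameter-space positions (0 outside the sheet bands)
phantom_region_label <- function(u, v, w, scheme = default_label_scheme) {
  lab <- integer(length(u))
  on_sheet_uv <- u >= .p_u["cap0"] & u <= .p_u["cap1"] &
    v >= .p_v["edge0"] & v <= .p_v["dg1"]
  gm_uv <- u >= .p_u["gm0"] & u <= .p_u["gm1"] &
    v >= .p_v["gm0"] & v <= .p_v["gm1"]
  mid <- w >= 0 & w <= 1
  lab[on_sheet_uv & w < 0 & w >= .p_w["srlm"]] <- scheme["SRLM"]
  lab[on_sheet_uv & w > 1 & w <= .p_w["pial"]] <- scheme["pial"]
  lab[on_sheet_uv & mid & u < .p_u["gm0"]] <- scheme["HATA"]
  lab[on_sheet_uv & mid & u > .p_u["gm1"]] <- scheme["IndGris"]
  lab[on_sheet_uv & mid & u >= .p_u["gm0"] & u <= .p_u["gm1"] &
        v < .p_v["gm0"]] <- scheme["MTLc"]
  lab[on_sheet_uv & mid & u >= .p_u["gm0"] & u <= .p_u["gm1"] &
        v > .p_v["gm1"]] <- scheme["DGgranule"]
  lab[gm_uv & mid] <- scheme["GM"]
  lab
}

#' Generate a folded-sheet phantom labelmap with ground truth
#'
#' Rasterizes the parametric sheet into the cropped grid: grey matter with
#' HATA / IndGris caps at the AP ends, an MTLc strip at the proximal edge, a
#' DG granule band at the distal edge, SRLM lining the concave face, pial on
#' the convex face, and optional cyst inclusions.  Deterministic given the
#' seed.
#'
#' @param params a [phantom_params()]
#' @return list with `labelmap` (a [tissue_labelmap()]) and `truth`
#'   (class `phantom_truth`): generative `true_ap`, `true_pd`, `true_depth`
#'   on GM voxels, DG parameter fields, and the analytic GM volume (mm^3)
#' @export
generate_phantom <- function(params) {
  p <- params
  dims <- p$grid_shape
  vs <- p$voxel_size
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -(dims / 2 - 0.5) * vs
  h <- vs / 3
  u <- seq(0, 1, length.out = ceiling(p$length / h) + 1)
  v <- seq(0, 1, length.out = ceiling(p$width / h) + 1)
  wspan <- (.p_w["pial"] - .p_w["srlm"]) * p$thickness
  w <- seq(.p_w["srlm"], .p_w["pial"], length.out = ceiling(wspan / h) + 1)
  n <- length(u) * length(v) * length(w)
  U <- rep(u, times = length(v) * length(w))
  V <- rep(rep(v, each = length(u)), times = length(w))
  W <- rep(w, each = length(u) * length(v))
  lab <- phantom_region_label(U, V, W)
  keep <- lab != 0L
  U <- U[keep]; V <- V[keep]; W <- W[keep]; lab <- lab[keep]
  world <- phantom_surface(p, U, V, W)
  vox <- world_to_voxel(affine, world)
  ijk <- round(vox)
  oob <- ijk < 0 | sweep(ijk, 2, dims - 1L, `>`)
  if (any(oob)) {
    over <- max(abs(vox - (dims[2] / 2)) / (dims / 2))
    stop("phantom sheet exceeds the grid; reduce length/width/curl by about ",
         signif(1 / over, 2), "x or enlarge grid_shape")
  }
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1
  d2 <- rowSums((vox - ijk)^2)
  o <- order(d2)
  first <- o[!duplicated(lin[o])]
  data <- integer(prod(dims))
  data[lin[first]] <- lab[first]
  ap_t <- rep(NaN, prod(dims)); pd_t <- ap_t; dp_t <- ap_t
  gm_sel <- first[lab[first] == default_label_scheme["GM"]]
  ap_t[lin[gm_sel]] <- (U[gm_sel] - .p_u["gm0"]) / (.p_u["gm1"] - .p_u["gm0"])
  pd_t[lin[gm_sel]] <- (V[gm_sel] - .p_v["gm0"]) / (.p_v["gm1"] - .p_v["gm0"])
  dp_t[lin[gm_sel]] <- W[gm_sel]
  dg_sel <- first[lab[first] == default_label_scheme["DGgranule"]]
  dg_ap <- rep(NaN, prod(dims)); dg_pd <- dg_ap; dg_io <- dg_ap
  dg_ap[lin[dg_sel]] <- (U[dg_sel] - .p_u["gm0"]) / (.p_u["gm1"] - .p_u["gm0"])
  dg_pd[lin[dg_sel]] <- W[dg_sel]  # PD and IO are swapped in the DG
  dg_io[lin[dg_sel]] <- (V[dg_sel] - .p_v["gm1"]) / (.p_v["dg1"] - .p_v["gm1"])
  # cyst inclusions inside GM (parameter-space balls, scaled to mm)
  cyst_vol <- 0
  if (p$n_cysts > 0) {
    centers <- with_local_seed(p$seed, cbind(runif(p$n_cysts, 0.3, 0.7),
                                             runif(p$n_cysts, 0.35, 0.65),
                                             runif(p$n_cysts, 0.45, 0.55)))
    gm_lin <- lin[gm_sel]
    du <- (U[gm_sel]); dv <- (V[gm_sel]); dw <- (W[gm_sel])
    rw <- min(p$cyst_radius, 0.25 * p$thickness)  # flattened inside the sheet
    for (ci in seq_len(p$n_cysts)) {
      d2c <- ((du - centers[ci, 1]) * p$length / p$cyst_radius)^2 +
        ((dv - centers[ci, 2]) * p$width / p$cyst_radius)^2 +
        ((dw - centers[ci, 3]) * p$thickness / rw)^2
      inside <- d2c < 1
      data[gm_lin[inside]] <- default_label_scheme["cyst"]
      ap_t[gm_lin[inside]] <- NaN
      pd_t[gm_lin[inside]] <- NaN
      dp_t[gm_lin[inside]] <- NaN
      cyst_vol <- cyst_vol + 4 / 3 * pi * p$cyst_radius^2 * rw
    }
  }
  lm <- tissue_labelmap(array(data, dims), affine, hemisphere = "R")
  truth <- structure(list(
    true_ap = array(ap_t, dims), true_pd = array(pd_t, dims),
    true_depth = array(dp_t, dims),
    dg = list(ap = array(dg_ap, dims), pd = array(dg_pd, dims),
              io = array(dg_io, dims)),
    expected_gm_volume = (.p_u["gm1"] - .p_u["gm0"]) * p$length *
      (.p_v["gm1"] - .p_v["gm0"]) * p$width * p$thickness - cyst_vol,
    params = p), class = "phantom_truth")
  if (p$hemisphere == "L") {
    lm <- flip_hemisphere(lm)
    lm$hemisphere <- "L"
    fl <- function(a) a[dims[1]:1, , , drop = FALSE]
    truth$true_ap <- fl(truth$true_ap); truth$true_pd <- fl(truth$true_pd)
    truth$true_depth <- fl(truth$true_depth)
    truth$dg <- lapply(truth$dg, fl)
  }
  list(labelmap = lm, truth = truth)
}

#' Generate an idealized template shape
#'
#' A smooth (undigitated, cyst-free) phantom with analytic DG coordinate
#' fields attached, for use in template shape injection.  In the DG the PD
#' and IO axes are swapped relative to the hippocampus proper: the DG's PD
#' runs across the granule sheet thickness and its IO along the band.
#'
#' @param params a [phantom_params()]; digitations and cysts are removed
#' @return a [template_shape()]
#' @export
generate_template <- function(params) {
  p <- params
  p$n_digitations <- 0L
  p$digitation_amplitude <- 0
  p$n_cysts <- 0L
  ph <- generate_phantom(p)
  dg_mask <- label_mask(ph$labelmap, "DGgranule")
  dg_fields <- coord_fields(ph$truth$dg$ap, ph$truth$dg$pd, ph$truth$dg$io,
                            dg_mask, io_mode = "laplace")
  template_shape(ph$labelmap, dg_fields,
                 metadata = list(params = p, kind = "synthetic idealized sheet"))
}

#' Analytic native midthickness area of a phantom
#'
#' Integrates the generative surface's area element over the GM (u, v)
#' range at mid-depth on a fine parameter grid.  Serves as the independent
#' reference for the global gyrification (native / unfolded area) ratio.
#'
#' @param params a [phantom_params()]
#' @param n integration grid size per axis
#' @return area in mm^2
#' @export
phantom_native_area <- function(params, n = 512L) {
  us <- seq(.p_u["gm0"], .p_u["gm1"], length.out = n)
  vs <- seq(.p_v["gm0"], .p_v["gm1"], length.out = n)
  U <- rep(us, times = n); V <- rep(vs, each = n)
  eps <- 1e-5
  pu <- (phantom_surface(params, U + eps, V, 0.5) -
           phantom_surface(params, U - eps, V, 0.5)) / (2 * eps)
  pv <- (phantom_surface(params, U, V + eps, 0.5) -
           phantom_surface(params, U, V - eps, 0.5)) / (2 * eps)
  cr <- cbind(pu[, 2] * pv[, 3] - pu[, 3] * pv[, 2],
              pu[, 3] * pv[, 1] - pu[, 1] * pv[, 3],
              pu[, 1] * pv[, 2] - pu[, 2] * pv[, 1])
  el <- sqrt(rowSums(cr^2))
  mean(el) * diff(range(us)) * diff(range(vs))
}

#' Synthetic quantitative image over a phantom
#'
#' A "myelin-like" contrast: brightest in the SRLM, decreasing with laminar
#' depth across GM (2 at the inner boundary down to 1 at the outer), zero
#' outside the sheet.  Used to exercise volume-to-surface sampling.
#'
#' @param lm phantom [tissue_labelmap()]
#' @param truth matching `phantom_truth`
#' @return `list(data, affine)` image in the phantom grid
#' @export
phantom_quantitative_image <- function(lm, truth) {
  img <- array(0, dim(lm$data))
  gm <- is.finite(truth$true_depth)
  img[gm] <- 2 - truth$true_depth[gm]
  img[label_mask(lm, "SRLM")] <- 2.5
  img[label_mask(lm, "pial")] <- 0.8
  list(data = img, affine = lm$affine)
}

#' Write a complete phantom fixture directory
#'
#' Emits the labelmap, truth volumes, template labelmap and DG fields, and a
#' quantitative image as NIfTI files under `dir`.
#'
#' @param params a [phantom_params()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_phantom_fixtures <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(params)
  write_labelmap(ph$labelmap, file.path(dir, "phantom_dseg.nii.gz"))
  for (nm in c("true_ap", "true_pd", "true_depth")) {
    a <- ph$truth[[nm]]; a[!is.finite(a)] <- -1
    write_nifti_volume(a, file.path(dir, paste0("phantom_", nm, ".nii.gz")),
                       affine = ph$labelmap$affine)
  }
  tpl <- generate_template(params)
  write_labelmap(tpl$labelmap, file.path(dir, "template_dseg.nii.gz"))
  qi <- phantom_quantitative_image(ph$labelmap, ph$truth)
  write_nifti_volume(qi$data, file.path(dir, "phantom_qmri.nii.gz"),
                     affine = qi$affine)
  invisible(dir)
}
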