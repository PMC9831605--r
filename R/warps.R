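# Dense displacement fields between native world space and the standardized
# unfolded prism, their ITK-convention NIfTI serialization, and application
# to images and meshes.

#' Warp field container
#'
#' A dense displacement field (mm) on a reference grid.  For
#' `native_to_unfolded` the reference is the native labelmap grid; for
#' `unfolded_to_native` it is the unfolded prism grid.  Displacements are
#' stored in RAS world convention; the ITK writer converts to LPS.
#'
#' @param displacement 4D array `(nx, ny, nz, 3)` of displacements in mm
#' @param direction `"native_to_unfolded"` or `"unfolded_to_native"`
#' @param ref_affine 4x4 voxel-to-world affine of the reference grid
#' @return object of class `warp_field`
#' @export
warp_field <- function(displacement,
                       direction = c("native_to_unfolded", "unfolded_to_native"),
                       ref_affine) {
  direction <- match.arg(direction)
  stopifnot(length(dim(displacement)) == 4L, dim(displacement)[4] == 3L)
  if (!all(is.finite(displacement))) stop("displacement field contains non-finite values")
  structure(list(displacement = displacement, direction = direction,
                 ref_shape = dim(displacement)[1:3], ref_affine = ref_affine),
            class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  cat("<warp_field> ", x$direction, ", grid ",
      paste(x$ref_shape, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Build the native-to-unfolded displacement field
#'
#' For every GM voxel the displacement is its scaled unfolded coordinate
#' minus its native world coordinate.  Outside GM the field is made dense by
#' nearest-GM extrapolation followed by a 1-voxel Gaussian smoothing of the
#' filled region (GM values are kept exact).
#'
#' @param fields a [coord_fields()] over the labelmap
#' @param lm the [tissue_labelmap()]
#' @param spec an [unfolded_space_spec()]
#' @param smooth_fill_sigma smoothing of extrapolated voxels, in voxels
#' @return a [warp_field()] on the native grid
#' @export
build_native_to_unfolded <- function(fields, lm,
                                     spec = unfolded_space_spec("hipp"),
                                     smooth_fill_sigma = 1) {
  dims <- dim(lm$data)
  gm <- as.vector(fields$domain_mask)
  if (!any(gm)) stop("empty coordinate domain")
  coords <- cbind(fields$ap[gm], fields$pd[gm], fields$io[gm])
  coords[coords < 0] <- 0; coords[coords > 1] <- 1
  unf <- scale_to_unfolded(coords, spec)
  world_all <- voxel_to_world(lm$affine, voxel_grid(dims))
  vals <- matrix(0, nrow = prod(dims), ncol = 3)
  vals[gm, ] <- unf - world_all[gm, , drop = FALSE]
  filled <- cpp_nearest_fill(vals, gm, dims)
  if (smooth_fill_sigma > 0) {
    for (c in 1:3) {
      sm <- cpp_gaussian_smooth(filled[, c], dims, rep(smooth_fill_sigma, 3))
      sm[gm] <- filled[gm, c]  # smoothing restricted to filled voxels
      filled[, c] <- sm
    }
  }
  warp_field(array(filled, c(dims, 3L)), "native_to_unfolded", lm$affine)
}

#' Build the unfolded-to-native displacement field
#'
#' GM voxels are treated as scattered samples located at their scaled
#' unfolded coordinates with their native world coordinates as values.  The
#' native position at each unfolded grid point is evaluated by deterministic
#' k-nearest-neighbour moving-least-squares local affine interpolation
#' (exact for affine coordinate maps); points beyond the sample cloud take
#' the local affine extension of the nearest samples, so the field is dense
#' and finite everywhere.
#'
#' @param fields a [coord_fields()]
#' @param lm the [tissue_labelmap()]
#' @param spec an [unfolded_space_spec()]
#' @param k neighbourhood size of the local fit
#' @return a [warp_field()] on the unfolded grid
#' @export
build_unfolded_to_native <- function(fields, lm,
                                     spec = unfolded_space_spec("hipp"),
                                     k = 16L) {
  dims <- dim(lm$data)
  gm <- as.vector(fields$domain_mask)
  coords <- cbind(fields$ap[gm], fields$pd[gm], fields$io[gm])
  keep <- stats::complete.cases(coords)
  coords <- coords[keep, , drop = FALSE]
  coords[coords < 0] <- 0; coords[coords > 1] <- 1
  if (nrow(coords) < 4) stop("fewer than 4 coordinate samples")
  sites <- scale_to_unfolded(coords, spec)
  ctr <- sweep(sites, 2, colMeans(sites))
  if (qr(ctr)$rank < 3) stop("coordinate samples are coplanar")
  values <- voxel_to_world(lm$affine, voxel_grid(dims)[gm, , drop = FALSE][keep, , drop = FALSE])
  queries <- voxel_to_world(spec$affine, voxel_grid(spec$shape))
  cell <- max(mean(lm$voxel_size),
              (prod(pmax(apply(sites, 2, function(s) diff(range(s))), 1e-6)) /
                 nrow(sites))^(1/3) * 2)
  nat <- cpp_mls_interp(sites, values, queries, as.integer(k), cell)
  warp_field(array(nat - queries, c(spec$shape, 3L)),
             "unfolded_to_native", spec$affine)
}

#' Write a warp as an ITK displacement-field NIfTI
#'
#' Writes a 5D `(X, Y, Z, 1, 3)` double-precision vector volume with the
#' displacement-field intent code (displacements round-trip bit-exactly).  Vectors follow the ITK physical (LPS)
#' convention: the first two RAS components are negated.  With
#' `format = "plain"` a 4D RAS field is written instead.
#'
#' @param w a [warp_field()]
#' @param path output `.nii`/`.nii.gz` path
#' @param format `"itk"` (default) or `"plain"`
#' @export
write_itk_warp <- function(w, path, format = c("itk", "plain")) {
  format <- match.arg(format)
  d <- w$ref_shape
  if (format == "plain") {
    arr <- w$displacement
  } else {
    arr <- array(w$displacement, c(d, 1L, 3L))
    arr[, , , , 1] <- -arr[, , , , 1]
    arr[, , , , 2] <- -arr[, , , , 2]
  }
  img <- RNifti::asNifti(arr)
  img$intent_code <- 1006L  # NIFTI_INTENT_DISPVECT; set before the transform
  spacing <- sqrt(colSums(w$ref_affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3))
  img <- RNifti::`qform<-`(img, structure(w$ref_affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(w$ref_affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a warp written by [write_itk_warp()]
#'
#' @param path file path
#' @param direction the direction to attach to the warp
#' @param format `"itk"` or `"plain"`, matching how the file was written
#' @return a [warp_field()]
#' @export
read_itk_warp <- function(path, direction, format = c("itk", "plain")) {
  format <- match.arg(format)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  d <- dim(arr)
  if (format == "itk") {
    if (length(d) != 5L || d[4] != 1L || d[5] != 3L)
      stop("expected 5D (X,Y,Z,1,3) displacement volume")
    arr <- array(arr, c(d[1:3], 3L))
    arr[, , , 1] <- -arr[, , , 1]
    arr[, , , 2] <- -arr[, , , 2]
  } else if (length(d) != 4L || d[4] != 3L) {
    stop("expected 4D (X,Y,Z,3) displacement volume")
  }
  warp_field(arr, direction, unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Displace points through a warp field
#'
#' Interpolates the displacement field (trilinear) at each point and adds it.
#' Points outside the reference grid use the displacement at the nearest
#' grid position (clamped sampling).
#'
#' @param w a [warp_field()]
#' @param pts n x 3 world coordinates (mm) in the warp's source space
#' @return n x 3 displaced world coordinates
#' @export
transform_points <- function(w, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  vox <- world_to_voxel(w$ref_affine, pts)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), w$ref_shape[a] - 1)
  disp <- vapply(1:3, function(c)
    cpp_trilinear(as.vector(w$displacement[, , , c]), w$ref_shape, vox),
    numeric(nrow(pts)))
  pts + disp
}

#' Apply a warp to an image or a surface mesh
#'
#' Images are resampled onto the warp's reference grid by pulling values
#' through the displacement (for an `unfolded_to_native` warp this maps a
#' native image into unfolded space, and vice versa).  Meshes are transformed
#' by moving each vertex by the interpolated displacement at its position;
#' the mesh `space` field must match the warp direction.
#'
#' @param target a [surface_mesh()], [tissue_labelmap()], or
#'   `list(data = 3D array, affine = 4x4)`
#' @param w a [warp_field()]
#' @param interpolation `"linear"` or `"nearest"` (images only)
#' @return transformed object of the same kind
#' @export
apply_warp <- function(target, w, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(target, "surface_mesh")) {
    need <- if (w$direction == "unfolded_to_native") "unfolded" else "native"
    if (target$space != need)
      stop("mesh is in ", target$space, " space but warp expects ", need)
    out <- target
    out$vertices <- transform_points(w, target$vertices)
    out$space <- if (need == "unfolded") "native" else "unfolded"
    return(out)
  }
  if (inherits(target, "tissue_labelmap")) {
    src <- list(data = target$data, affine = target$affine)
    interpolation <- "nearest"
  } else src <- target
  dims <- w$ref_shape
  ref_world <- voxel_to_world(w$ref_affine, voxel_grid(dims))
  pulled <- ref_world + matrix(w$displacement, ncol = 3)
  vox <- world_to_voxel(src$affine, pulled)
  vals <- if (interpolation == "nearest")
    cpp_nearest_sample(as.vector(src$data), dim(src$data), vox)
  else cpp_trilinear(as.numeric(src$data), dim(src$data), vox)
  vals[is.na(vals)] <- 0
  out <- list(data = array(vals, dims), affine = w$ref_affine)
  if (inherits(target, "tissue_labelmap"))
    out <- tissue_labelmap(array(as.integer(round(out$data)), dims),
                           w$ref_affine, target$label_scheme, target$hemisphere)
  out
}
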