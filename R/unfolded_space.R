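# Standardized unfolded space: a rectangular prism spanned by the AP, PD and
# IO coordinates.

#' Unfolded-space specification
#'
#' The standardized unfolded space is a rectangular prism of 256 x 128 x 16
#' voxels (AP, PD, IO) for the hippocampus, or 256 x 32 x 16 for the dentate
#' gyrus, at 0.15625 mm isotropic.  The AP:PD aspect ratio of the hippocampal
#' prism is 2:1, reflecting that the structure is longer than it is wide.
#' The prism origin sits at (0,0,0) mm in its own space with a diagonal
#' affine; this origin is a package convention.
#'
#' @param structure `"hipp"` or `"dg"`
#' @param shape optional voxel dimensions override (AP, PD, IO)
#' @param voxel_size voxel size in mm (isotropic)
#' @param origin world position of the first voxel center, mm
#' @return object of class `unfolded_space_spec` with fields `shape`,
#'   `voxel_size`, `origin`, `extent` (mm) and `affine`
#' @export
unfolded_space_spec <- function(structure = c("hipp", "dg"), shape = NULL,
                                voxel_size = 0.15625, origin = c(0, 0, 0)) {
  structure <- match.arg(structure)
  if (is.null(shape))
    shape <- if (structure == "hipp") c(256L, 128L, 16L) else c(256L, 32L, 16L)
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- origin
  out <- list(structure = structure, shape = as.integer(shape),
              voxel_size = voxel_size, origin = origin,
              extent = shape * voxel_size, affine = affine)
  class(out) <- "unfolded_space_spec"
  out
}

#' Map unit-cube coordinates to unfolded world coordinates
#'
#' Scales normalized (AP, PD, IO) coordinates in `[0,1]` to the physical
#' extent of the standardized unfolded prism:
#' `c_k = origin_k + v_k * shape_k * voxel_size`.
#'
#' @param coords n x 3 matrix (or length-3 vector) of (AP, PD, IO) in `[0,1]`
#' @param spec an [unfolded_space_spec()]
#' @return n x 3 matrix of world coordinates (mm) in unfolded space
#' @export
scale_to_unfolded <- function(coords, spec) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  rng <- range(coords, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("coordinates outside [0,1]")
  sweep(sweep(coords, 2, spec$extent, `*`), 2, spec$origin, `+`)
}

# inverse of scale_to_unfolded (world mm -> unit cube)
unscale_from_unfolded <- function(xyz, spec) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, spec$origin, `-`), 2, spec$extent, `/`)
}
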