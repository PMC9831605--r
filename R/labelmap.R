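# Domain types and NIfTI I/O for tissue-class labelmaps.

#' Default tissue label scheme
#'
#' Integer codes for the hippocampal tissue classes used throughout the
#' package: grey matter (GM), stratum radiatum/lacunosum/moleculare (SRLM),
#' cysts, the dentate gyrus granule cell layer (DGgranule), medial temporal
#' lobe cortex (MTLc), pial surface, hippocampal-amygdalar transition area
#' (HATA) and indusium griseum (IndGris).  The class inventory is anatomical;
#' the integer assignment is a package convention and can be overridden with
#' a JSON label-scheme file (see [read_label_scheme()]).
#'
#' @export
default_label_scheme <- c(
  background = 0L, GM = 1L, SRLM = 2L, cyst = 3L, DGgranule = 4L,
  MTLc = 5L, pial = 6L, HATA = 7L, IndGris = 8L
)

required_labels <- c("GM", "SRLM", "HATA", "IndGris", "MTLc", "DGgranule")

#' Construct a tissue labelmap
#'
#' @param data 3D integer array of voxel labels
#' @param affine 4x4 voxel-to-world transform (mm, RAS, 0-based indices)
#' @param label_scheme named integer vector mapping tissue names to values
#' @param hemisphere `"L"` or `"R"`
#' @return an object of class `tissue_labelmap`
#' @export
tissue_labelmap <- function(data, affine, label_scheme = default_label_scheme,
                            hemisphere = "R") {
  if (length(dim(data)) != 3L) stop("expected 3D labelmap")
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (!hemisphere %in% c("L", "R")) stop("hemisphere must be 'L' or 'R'")
  storage.mode(data) <- "integer"
  structure(list(
    data = data,
    affine = affine,
    label_scheme = label_scheme,
    hemisphere = hemisphere,
    voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))
  ), class = "tissue_labelmap")
}

#' @export
print.tissue_labelmap <- function(x, ...) {
  cat("<tissue_labelmap> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm, hemi-", x$hemisphere, "\n", sep = "")
  tab <- table(factor(x$data[x$data != 0],
                      levels = x$label_scheme[x$label_scheme != 0],
                      labels = names(x$label_scheme)[x$label_scheme != 0]))
  print(tab)
  invisible(x)
}

# mask for one or more tissue names
label_mask <- function(lm, names) {
  vals <- lm$label_scheme[names]
  if (anyNA(vals)) stop("unknown tissue name(s): ",
                        paste(names[is.na(vals)], collapse = ", "))
  array(lm$data %in% vals, dim(lm$data))
}

#' Read a labelmap from a NIfTI volume
#'
#' The volume must be 3D with integer-valued data.  Unknown label values do
#' not cause a read error; they are reported by [validate_labelmap()].
#'
#' @param path path to a `.nii` / `.nii.gz` file
#' @param label_scheme named integer vector, defaults to the package scheme
#' @param hemisphere hemisphere flag to attach
#' @return a [tissue_labelmap()]
#' @export
read_labelmap <- function(path, label_scheme = default_label_scheme,
                          hemisphere = "R") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  else if (length(d) != 3L) stop("expected 3D labelmap, got ", length(d), "D")
  arr <- as.array(img)
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("labelmap contains non-integer values")
  tissue_labelmap(array(as.integer(round(arr)), dim(arr)),
                  affine = unclass(RNifti::xform(img))[1:4, 1:4],
                  label_scheme = label_scheme, hemisphere = hemisphere)
}

#' Write a volume (labelmap or plain array) as NIfTI
#'
#' @param x a `tissue_labelmap`, or a numeric/integer 3D array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param affine 4x4 affine, required when `x` is a bare array
#' @param datatype NIfTI on-disk datatype
#' @export
write_nifti_volume <- function(x, path, affine = NULL, datatype = "auto") {
  if (inherits(x, "tissue_labelmap")) {
    affine <- x$affine
    x <- x$data
    if (datatype == "auto") datatype <- "int16"
  }
  if (is.null(affine)) stop("affine required")
  if (datatype == "auto") datatype <- "float"
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
write_labelmap <- function(x, path) write_nifti_volume(x, path)

#' Read a label scheme from a JSON file
#'
#' The file maps tissue names to integers, e.g.
#' `{"background": 0, "GM": 1, ...}`.
#'
#' @param path JSON file path
#' @return named integer vector
#' @export
read_label_scheme <- function(path) {
  x <- jsonlite::read_json(path)
  out <- vapply(x, function(v) as.integer(v), integer(1))
  names(out) <- names(x)
  out
}

#' Mirror a labelmap across hemispheres
#'
#' Reverses the sagittal (first) voxel axis and updates the affine so that
#' world coordinates are mirrored about the x = 0 plane; the hemisphere flag
#' is toggled.  Applying the flip twice returns the original labelmap.
#'
#' @param lm a [tissue_labelmap()]
#' @param to optionally, the hemisphere to flip to; if `lm` is already in
#'   that hemisphere the labelmap is returned unchanged
#' @return the flipped [tissue_labelmap()]
#' @export
flip_hemisphere <- function(lm, to = NULL) {
  if (!is.null(to) && lm$hemisphere == to) return(lm)
  nx <- dim(lm$data)[1]
  data <- lm$data[nx:1, , , drop = FALSE]
  # new index i' relates to old index i = (nx-1) - i'
  flip_idx <- diag(c(-1, 1, 1, 1)); flip_idx[1, 4] <- nx - 1
  mirror_world <- diag(c(-1, 1, 1, 1))
  affine <- mirror_world %*% lm$affine %*% flip_idx
  out <- tissue_labelmap(data, affine, lm$label_scheme,
                         hemisphere = if (lm$hemisphere == "L") "R" else "L")
  out
}

#' Validation report for a labelmap
#'
#' Reports required tissue labels that are absent, the number of 26-connected
#' grey-matter components, and any voxel values outside the label scheme.
#' Purely diagnostic: never raises an error.
#'
#' @param lm a [tissue_labelmap()]
#' @return an object of class `validation_report` with fields
#'   `missing_labels`, `gm_component_count`, `warnings`
#' @export
validate_labelmap <- function(lm) {
  present <- unique(as.vector(lm$data))
  missing <- required_labels[!lm$label_scheme[required_labels] %in% present]
  unknown <- setdiff(present, lm$label_scheme)
  warnings <- character(0)
  if (length(unknown))
    warnings <- c(warnings, paste0("unknown label value(s): ",
                                   paste(sort(unknown), collapse = ", ")))
  gm <- label_mask(lm, "GM")
  ncomp <- 0L
  if (any(gm)) {
    labs <- cpp_label_components(as.vector(gm), dim(gm), 26L)
    ncomp <- max(labs)
    if (ncomp > 1L)
      warnings <- c(warnings, paste0("GM has ", ncomp, " connected components"))
  }
  structure(list(missing_labels = missing, gm_component_count = ncomp,
                 warnings = warnings), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  missing labels:", if (length(x$missing_labels))
    paste(x$missing_labels, collapse = ", ") else "none", "\n")
  cat("  GM components:", x$gm_component_count, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
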