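# Unfolded subfield atlas application: the same unfolded-plane label image is
# applied identically to every subject, giving topologically constrained
# vertex and volumetric subfield labels.

#' Subfield atlas on the unfolded plane
#'
#' @param label_image 2D integer matrix over (AP, PD): rows index AP, columns
#'   index PD, both spanning `[0,1]`
#' @param label_names named integer vector mapping subfield names to values
#' @param provenance free-text description of the atlas origin
#' @return object of class `subfield_atlas`
#' @export
subfield_atlas <- function(label_image, label_names, provenance = "") {
  label_image <- as.matrix(label_image)
  storage.mode(label_image) <- "integer"
  if (any(!label_image %in% label_names))
    stop("atlas contains pixels outside label_names")
  structure(list(label_image = label_image, label_names = label_names,
                 provenance = provenance), class = "subfield_atlas")
}

#' @export
print.subfield_atlas <- function(x, ...) {
  cat("<subfield_atlas> ", paste(dim(x$label_image), collapse = " x "),
      " (AP x PD), labels: ", paste(names(x$label_names), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Schematic proximal-distal banded subfield atlas
#'
#' Builds a five-band atlas (Sub, CA1, CA2, CA3, CA4) with bands running the
#' full AP extent and widths given as PD fractions.  This is a synthetic
#' stand-in with the canonical band ordering; any labelled unfolded image can
#' be dropped in via [subfield_atlas()] or [read_atlas()].
#'
#' @param band_fractions PD widths of the five bands; must sum to 1.  The
#'   defaults loosely mimic the canonical unfolded layout (wide Sub/CA1,
#'   narrow CA2).
#' @param shape atlas pixel grid (AP, PD)
#' @return a [subfield_atlas()]
#' @export
make_schematic_atlas <- function(band_fractions = c(Sub = 0.30, CA1 = 0.32,
                                                    CA2 = 0.10, CA3 = 0.15,
                                                    CA4 = 0.13),
                                 shape = c(256L, 128L)) {
  if (any(band_fractions <= 0) || abs(sum(band_fractions) - 1) > 1e-6)
    stop("band fractions must be positive and sum to 1")
  if (is.null(names(band_fractions)))
    names(band_fractions) <- paste0("band", seq_along(band_fractions))
  label_names <- seq_along(band_fractions)
  names(label_names) <- names(band_fractions)
  edges <- cumsum(c(0, band_fractions))
  pd <- (seq_len(shape[2]) - 0.5) / shape[2]
  band <- findInterval(pd, edges, rightmost.closed = TRUE)
  img <- matrix(rep(band, each = shape[1]), shape[1], shape[2])
  subfield_atlas(img, label_names, provenance = "synthetic schematic bands")
}

#' Read an unfolded atlas from a 2D NIfTI label image
#'
#' @param path NIfTI file whose first two dimensions are (AP, PD)
#' @param label_names named integer vector; defaults to the values present
#' @return a [subfield_atlas()]
#' @export
read_atlas <- function(path, label_names = NULL) {
  img <- as.array(RNifti::readNifti(path))
  d <- dim(img)
  if (length(d) == 3L && d[3] == 1L) dim(img) <- d[1:2]
  if (length(dim(img)) != 2L) stop("expected a 2D atlas image")
  if (is.null(label_names)) {
    vals <- sort(unique(as.vector(img)))
    label_names <- as.integer(vals)
    names(label_names) <- paste0("label", vals)
  }
  subfield_atlas(matrix(as.integer(round(img)), nrow(img)), label_names,
                 provenance = path)
}

# nearest-pixel atlas lookup for normalized (ap, pd) in [0,1]
atlas_lookup <- function(atlas, ap, pd) {
  d <- dim(atlas$label_image)
  if (any(ap < -1e-6 | ap > 1 + 1e-6 | pd < -1e-6 | pd > 1 + 1e-6, na.rm = TRUE))
    stop("coordinates outside the atlas extent")
  i <- pmin(pmax(floor(ap * d[1]) + 1L, 1L), d[1])
  j <- pmin(pmax(floor(pd * d[2]) + 1L, 1L), d[2])
  atlas$label_image[cbind(i, j)]
}

#' Label mesh vertices from an unfolded atlas
#'
#' Nearest-pixel lookup of each vertex's normalized (AP, PD) position in the
#' atlas image.  Identical for every subject by construction.
#'
#' @param atlas a [subfield_atlas()]
#' @param mesh a [surface_mesh()] carrying unfolded coordinates
#' @return integer vector of vertex labels (length = vertex count)
#' @export
label_vertices <- function(atlas, mesh) {
  uc <- mesh$unfolded_coords
  if (is.null(uc)) stop("mesh carries no unfolded coordinates")
  atlas_lookup(atlas, uc[, 1], uc[, 2])
}

#' Fill volumetric subfields between the inner and outer surfaces
#'
#' Every GM voxel receives the atlas label at its (AP, PD) coordinate; DG
#' voxels (granule-layer label) receive a dedicated DG label; all other
#' voxels are untouched (0).  Voxels whose coordinates are undefined fall
#' back to the nearest coordinate-bearing voxel (count in attribute
#' `n_fallback`).
#'
#' @param atlas a [subfield_atlas()]
#' @param fields a [coord_fields()] over GM
#' @param lm the [tissue_labelmap()]
#' @param dg_label integer label value to use for the DG (default: one past
#'   the largest atlas label)
#' @return a [tissue_labelmap()] whose scheme is the subfield labels
#' @export
fill_volumetric_subfields <- function(atlas, fields, lm, dg_label = NULL) {
  dims <- dim(lm$data)
  gm <- as.vector(fields$domain_mask)
  ap <- fields$ap[gm]; pd <- fields$pd[gm]
  bad <- !is.finite(ap) | !is.finite(pd)
  n_fallback <- sum(bad)
  if (n_fallback > 0) {
    # nearest-coordinate fallback: fill coordinates from defined GM voxels
    vals <- matrix(0, prod(dims), 2)
    vals[gm, 1] <- ifelse(bad, 0, ap)
    vals[gm, 2] <- ifelse(bad, 0, pd)
    known <- logical(prod(dims)); known[gm] <- !bad
    filled <- cpp_nearest_fill(vals, known, dims)
    ap <- filled[gm, 1]; pd <- filled[gm, 2]
  }
  ap <- pmin(pmax(ap, 0), 1); pd <- pmin(pmax(pd, 0), 1)
  out <- integer(prod(dims))
  out[gm] <- atlas_lookup(atlas, ap, pd)
  label_names <- atlas$label_names
  if (is.null(dg_label)) dg_label <- max(label_names) + 1L
  dg_mask <- as.vector(label_mask(lm, "DGgranule"))
  out[dg_mask] <- dg_label
  label_names <- c(label_names, DG = as.integer(dg_label))
  res <- tissue_labelmap(array(out, dims), lm$affine,
                         label_scheme = c(background = 0L, label_names),
                         hemisphere = lm$hemisphere)
  attr(res, "n_fallback") <- n_fallback
  res
}

canonical_band_order <- c("Sub", "CA1", "CA2", "CA3", "CA4", "DG")

#' Check the topology of a vertex labelling
#'
#' Computes connected components per label on the vertex graph (triangle
#' adjacency restricted to each label), flags labels with more than one
#' component, label pairs that touch although they are not neighbours in the
#' canonical proximal-distal ordering (Sub, CA1, CA2, CA3, CA4, DG), and
#' whether each label reaches both AP extremes of the mesh.
#'
#' @param labels integer vertex label vector
#' @param mesh the labelled [surface_mesh()]
#' @param label_names optional named integer vector for readable names
#' @param order canonical label ordering for adjacency checks
#' @return object of class `topology_report` with `components_per_label`,
#'   `adjacency_violations` and `full_ap_extent`
#' @export
check_topology <- function(labels, mesh, label_names = NULL,
                           order = canonical_band_order) {
  e <- mesh_edges(mesh)
  name_of <- function(v) {
    if (is.null(label_names)) as.character(v)
    else names(label_names)[match(v, label_names)]
  }
  vals <- sort(unique(labels))
  comps <- integer(0)
  for (v in vals) {
    vs <- which(labels == v)
    sub <- e[labels[e[, 1]] == v & labels[e[, 2]] == v, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(sub), vs), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(vs) - igraph::vcount(g)))
    comps[name_of(v)] <- as.integer(igraph::components(g)$no)
  }
  # adjacency violations against the canonical ordering
  viol <- character(0)
  cross <- e[labels[e[, 1]] != labels[e[, 2]], , drop = FALSE]
  if (nrow(cross)) {
    pr <- unique(cbind(pmin(labels[cross[, 1]], labels[cross[, 2]]),
                       pmax(labels[cross[, 1]], labels[cross[, 2]])))
    for (r in seq_len(nrow(pr))) {
      n1 <- name_of(pr[r, 1]); n2 <- name_of(pr[r, 2])
      p1 <- match(n1, order); p2 <- match(n2, order)
      if (!is.na(p1) && !is.na(p2) && abs(p1 - p2) > 1L)
        viol <- c(viol, paste(n1, n2, sep = "|"))
    }
  }
  # AP extent per label
  full_ap <- logical(length(vals))
  names(full_ap) <- name_of(vals)
  if (!is.null(mesh$unfolded_coords)) {
    ap <- mesh$unfolded_coords[, 1]
    ap_min <- min(ap); ap_max <- max(ap)
    for (i in seq_along(vals)) {
      v <- vals[i]
      full_ap[i] <- any(labels == v & ap <= ap_min + 1e-9) &&
        any(labels == v & ap >= ap_max - 1e-9)
    }
  }
  structure(list(components_per_label = comps, adjacency_violations = viol,
                 full_ap_extent = full_ap), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>\n  components per label: ",
      paste(names(x$components_per_label), x$components_per_label,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  adjacency violations:", if (length(x$adjacency_violations))
    paste(x$adjacency_violations, collapse = ", ") else "none", "\n")
  cat("  full AP extent:", paste(names(x$full_ap_extent)[x$full_ap_extent],
                                 collapse = ", "), "\n")
  invisible(x)
}
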