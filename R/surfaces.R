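# Unfolded tessellations, spacing-driven decimation, and folded (native)
# inner / midthickness / outer surfaces with positional vertex
# correspondence.

#' Surface mesh container
#'
#' An open triangulated sheet.  Vertex correspondence across layers (inner,
#' midthickness, outer) and across subjects is positional: meshes of the same
#' density share the triangle array and vertex ordering.
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @param space `"unfolded"` or `"native"`
#' @param density `"0p5mm"`, `"1mm"`, `"2mm"` or `"unfoldiso"`
#' @param structure `"hipp"` or `"dg"`
#' @param layer `"inner"`, `"midthickness"` or `"outer"` (optional)
#' @param unfolded_coords n x 2 matrix of normalized (AP, PD) per vertex
#' @param io_level normalized IO level the mesh was instantiated at
#' @return object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, triangles, space = "unfolded",
                         density = "unfoldiso", structure = "hipp",
                         layer = NULL, unfolded_coords = NULL,
                         io_level = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) && (max(triangles) > nrow(vertices) || min(triangles) < 1L))
    stop("triangle index out of range")
  out <- list(vertices = vertices, triangles = triangles, space = space,
              density = density, structure = structure, layer = layer,
              unfolded_coords = unfolded_coords, io_level = io_level)
  class(out) <- "surface_mesh"
  out
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ", x$space, " space, den-",
      x$density, if (!is.null(x$layer)) paste0(", ", x$layer), "\n", sep = "")
  invisible(x)
}

# unique undirected edges of a mesh, as a 2-column matrix of vertex indices
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# counts of incident triangles per undirected edge (manifold check: <= 2)
edge_triangle_counts <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

# median edge length of a mesh given vertex positions
median_edge_length <- function(positions, mesh) {
  e <- mesh_edges(mesh)
  d <- sqrt(rowSums((positions[e[, 1], , drop = FALSE] -
                       positions[e[, 2], , drop = FALSE])^2))
  stats::median(d)
}

#' Uniform grid tessellation of the unfolded plane
#'
#' Builds a `rows x cols` vertex grid spanning the full unfolded AP x PD
#' rectangle at a fixed IO level, with each quad split along the (+AP, +PD)
#' diagonal: `2 * (rows-1) * (cols-1)` triangles with consistent winding.
#' The legacy `unfoldiso` tessellations are 254 x 126 (hippocampus, 32,004
#' vertices) and 254 x 30 (DG, 7,620 vertices).
#'
#' @param rows,cols grid size along AP and PD (each >= 2)
#' @param io_level normalized IO level in `[0,1]` (default midthickness)
#' @param spec an [unfolded_space_spec()]
#' @param density density tag to attach
#' @return an unfolded-space [surface_mesh()]
#' @export
make_grid_mesh <- function(rows, cols, io_level = 0.5,
                           spec = unfolded_space_spec("hipp"),
                           density = "unfoldiso") {
  stopifnot(rows >= 2, cols >= 2)
  ap <- rep(seq(0, 1, length.out = rows), times = cols)
  pd <- rep(seq(0, 1, length.out = cols), each = rows)
  verts <- scale_to_unfolded(cbind(ap, pd, io_level), spec)
  i <- rep(seq_len(rows - 1L), times = cols - 1L)
  j <- rep(seq_len(cols - 1L), each = rows - 1L)
  v00 <- (j - 1L) * rows + i
  v10 <- v00 + 1L
  v01 <- v00 + rows
  v11 <- v01 + 1L
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface_mesh(verts, tris, space = "unfolded", density = density,
               structure = spec$structure,
               unfolded_coords = cbind(ap, pd), io_level = io_level)
}

#' Decimate a mesh to a target native vertex spacing
#'
#' Iteratively collapses the shortest edge measured in native space (the
#' spacing that matters to users of the folded surfaces) until the median
#' native edge length reaches `target_spacing`.  Boundary vertices are
#' preferentially preserved: an interior endpoint is always the one removed,
#' and boundary vertices are only removed by collapses along the boundary
#' itself.  A link-condition check keeps the sheet 2-manifold.  Deterministic
#' given its input.
#'
#' @param mesh a [surface_mesh()] (any space; vertex set is what is thinned)
#' @param native_positions n x 3 matrix: each vertex's position in native mm
#' @param target_spacing target median edge length in native mm
#' @return the decimated [surface_mesh()] (same space as input)
#' @export
decimate_to_spacing <- function(mesh, native_positions, target_spacing) {
  native_positions <- as.matrix(native_positions)
  if (nrow(native_positions) != nrow(mesh$vertices))
    stop("native_positions must match vertex count")
  cur <- median_edge_length(native_positions, mesh)
  if (target_spacing <= cur) {
    warning("target spacing ", target_spacing,
            " <= current median spacing ", signif(cur, 4), "; mesh unchanged")
    return(mesh)
  }
  uv <- mesh$unfolded_coords
  if (is.null(uv)) uv <- matrix(0, 0, 2)
  res <- cpp_decimate_edges(native_positions, uv, mesh$triangles - 1L,
                            target_spacing)
  kept <- res$kept
  idx_map <- cumsum(kept)
  out <- mesh
  out$vertices <- mesh$vertices[kept, , drop = FALSE]
  out$triangles <- matrix(idx_map[res$triangles + 1L], ncol = 3)
  if (!is.null(mesh$unfolded_coords))
    out$unfolded_coords <- mesh$unfolded_coords[kept, , drop = FALSE]
  out
}

density_target_mm <- c("0p5mm" = 0.5, "1mm" = 1, "2mm" = 2)

#' Build native inner / midthickness / outer surfaces
#'
#' Instantiates the requested density's unfolded tessellation at IO levels
#' 0, 0.5 and 1, and maps each through the unfolded-to-native warp.  For the
#' mm-spacing densities, the tessellation is first decimated against the
#' native midthickness geometry; `unfoldiso` skips decimation entirely.  All
#' three layers share the triangle array bit-exactly (positional vertex
#' correspondence).
#'
#' @param spec an [unfolded_space_spec()]
#' @param warp_u2n an `unfolded_to_native` [warp_field()]
#' @param density `"0p5mm"`, `"1mm"`, `"2mm"` or `"unfoldiso"`
#' @param base_grid starting tessellation (rows, cols); default the legacy
#'   unfoldiso grid
#' @return list with native `inner`, `midthickness`, `outer` meshes and the
#'   matching `unfolded_midthickness`
#' @export
build_layer_surfaces <- function(spec, warp_u2n,
                                 density = c("0p5mm", "1mm", "2mm", "unfoldiso"),
                                 base_grid = NULL) {
  density <- match.arg(density)
  if (is.null(base_grid))
    base_grid <- if (spec$structure == "dg") c(254L, 30L) else c(254L, 126L)
  base <- make_grid_mesh(base_grid[1], base_grid[2], io_level = 0.5,
                         spec = spec, density = density)
  if (density != "unfoldiso") {
    native_mid <- transform_points(warp_u2n, base$vertices)
    base <- decimate_to_spacing(base, native_mid, density_target_mm[density])
  }
  layers <- list(inner = 0, midthickness = 0.5, outer = 1)
  out <- lapply(names(layers), function(nm) {
    io <- layers[[nm]]
    verts <- scale_to_unfolded(cbind(base$unfolded_coords, io), spec)
    m <- surface_mesh(verts, base$triangles, space = "unfolded",
                      density = density, structure = spec$structure,
                      layer = nm, unfolded_coords = base$unfolded_coords,
                      io_level = io)
    apply_warp(m, warp_u2n)
  })
  names(out) <- names(layers)
  out$unfolded_midthickness <- surface_mesh(
    scale_to_unfolded(cbind(base$unfolded_coords, 0.5), spec),
    base$triangles, space = "unfolded", density = density,
    structure = spec$structure, layer = "midthickness",
    unfolded_coords = base$unfolded_coords, io_level = 0.5)
  out
}

#' Build dentate gyrus surfaces
#'
#' DG meshes are built over the narrower 256 x 32-aspect unfolded domain
#' (unfoldiso grid 254 x 30, 7,620 vertices).  The DG coordinate fields
#' normally come from template shape injection.  Thickness is not a
#' supported DG metric (see [thickness()]).
#'
#' @param spec_dg a `"dg"` [unfolded_space_spec()]
#' @param warp_u2n_dg the DG `unfolded_to_native` [warp_field()]
#' @param density density preset
#' @return list of meshes as in [build_layer_surfaces()]
#' @export
make_dg_surfaces <- function(spec_dg, warp_u2n_dg,
                             density = c("0p5mm", "1mm", "2mm", "unfoldiso")) {
  if (spec_dg$structure != "dg") stop("spec_dg must be a 'dg' space spec")
  build_layer_surfaces(spec_dg, warp_u2n_dg, density = match.arg(density))
}

# per-triangle unit normals and areas
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  list(normals = n / pmax(len, 1e-300), areas = len / 2)
}

# sparse vertex adjacency (one-ring) of a mesh
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}
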