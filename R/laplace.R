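# Laplace coordinate fields over the grey-matter voxel domain, and the
# equivolumetric replacement of the laminar (inner-outer) field.

#' Boundary conditions for one coordinate axis
#'
#' Source labels receive the Dirichlet value 0, sink labels the value 1;
#' everywhere else the domain border is treated as no-flux (Neumann).
#'
#' @param source_labels character vector of tissue names held at 0
#' @param sink_labels character vector of tissue names held at 1
#' @param axis one of `"AP"`, `"PD"`, `"IO"`
#' @return object of class `boundary_conditions`
#' @export
boundary_conditions <- function(source_labels, sink_labels,
                                axis = c("AP", "PD", "IO")) {
  axis <- match.arg(axis)
  if (!length(source_labels) || !length(sink_labels))
    stop("source and sink label sets must be non-empty")
  if (length(intersect(source_labels, sink_labels)))
    stop("source and sink label sets must be disjoint")
  structure(list(source_labels = source_labels, sink_labels = sink_labels,
                 axis = axis), class = "boundary_conditions")
}

#' Geodesic-distance initialization of a Laplace field
#'
#' Returns `d_src / (d_src + d_snk)` where the distances are multi-source
#' breadth-first (6-connected) geodesic distances within the domain from the
#' source and sink voxel sets.  This is a solver initialization that
#' accelerates relaxation; the converged field does not depend on it.
#' Domain voxels unreachable from both boundaries get 0.5 with a warning;
#' voxels reachable from only one boundary get that boundary's value.
#'
#' @param domain logical 3D array, the solve domain
#' @param source_mask,sink_mask logical 3D arrays of boundary-label voxels
#' @return numeric array, values in `[0,1]` on domain voxels, `NaN` outside
#' @export
init_field_geodesic <- function(domain, source_mask, sink_mask) {
  dims <- dim(domain)
  walk <- domain | source_mask | sink_mask
  d_src <- cpp_bfs_distance(as.vector(walk), as.vector(source_mask), dims)
  d_snk <- cpp_bfs_distance(as.vector(walk), as.vector(sink_mask), dims)
  f <- rep(NaN, length(domain))
  dv <- as.vector(domain)
  fs <- d_src[dv]; fk <- d_snk[dv]
  val <- fs / (fs + fk)
  val[is.infinite(fs) & is.finite(fk)] <- 1
  val[is.finite(fs) & is.infinite(fk)] <- 0
  iso <- is.infinite(fs) & is.infinite(fk)
  if (any(iso)) {
    warning(sum(iso), " domain voxel(s) unreachable from both boundaries; set to 0.5")
    val[iso] <- 0.5
  }
  f[dv] <- val
  array(f, dims)
}

#' Solve the discrete Laplace equation over a voxel domain
#'
#' Each domain voxel converges to the mean of its in-domain-or-boundary
#' neighbors, with Dirichlet values 0 on source voxels and 1 on sink voxels,
#' and no-flux (neighbor omitted) at all other domain borders.  Solved by
#' successive over-relaxation Gauss-Seidel sweeps; iteration stops when the
#' largest absolute update falls below `tol` or after `max_iter` sweeps.
#'
#' @param domain logical 3D array of solve-domain voxels
#' @param source_mask,sink_mask logical 3D arrays (Dirichlet 0 / 1)
#' @param tol maximum-update stopping tolerance
#' @param max_iter sweep budget
#' @param connectivity Laplacian stencil: 6 (default), 18 or 26 neighbors
#' @param omega over-relaxation factor
#' @param init optional initialization array; defaults to the geodesic
#'   initialization of [init_field_geodesic()]
#' @return numeric array with the solution on domain voxels, `NaN` elsewhere;
#'   attributes `iterations` and `max_update` record solver state
#' @export
solve_laplace <- function(domain, source_mask, sink_mask, tol = 1e-5,
                          max_iter = 10000L, connectivity = 6L, omega = 1.8,
                          init = NULL) {
  stopifnot(tol > 0)
  dims <- dim(domain)
  source_mask <- source_mask & !domain
  sink_mask <- sink_mask & !domain & !source_mask
  # endpoints must touch the domain
  d1 <- cpp_bfs_distance(as.vector(domain | source_mask),
                         as.vector(source_mask), dims)
  d2 <- cpp_bfs_distance(as.vector(domain | sink_mask),
                         as.vector(sink_mask), dims)
  if (!any(is.finite(d1[as.vector(domain)])) ||
      !any(is.finite(d2[as.vector(domain)])))
    stop("axis endpoints not connected to domain")
  if (is.null(init)) init <- init_field_geodesic(domain, source_mask, sink_mask)
  f0 <- as.vector(init)
  f0[!is.finite(f0)] <- 0.5
  code <- integer(length(domain))
  code[as.vector(domain)] <- 1L
  code[as.vector(source_mask)] <- 2L
  code[as.vector(sink_mask)] <- 3L
  res <- cpp_solve_laplace(f0, code, dims, omega, tol,
                           as.integer(max_iter), as.integer(connectivity))
  if (res$iterations >= max_iter)
    message("solve_laplace: max_iter reached (max update ",
            signif(res$max_update, 3), ")")
  f <- res$field
  f[code == 0L] <- NaN
  f[code == 2L] <- NaN; f[code == 3L] <- NaN
  f[as.vector(domain)] <- pmin(1, pmax(0, f[as.vector(domain)]))
  out <- array(f, dims)
  attr(out, "iterations") <- res$iterations
  attr(out, "max_update") <- res$max_update
  out
}

#' Equivolumetric remapping of the laminar Laplace fraction
#'
#' Replaces the Laplace laminar fraction `alpha` with the equivolumetric
#' depth `rho` between an inner and an outer surface of (local, per-column)
#' areas `A_in` and `A_out`:
#' `rho = (-A_in + sqrt(alpha * A_out^2 + (1 - alpha) * A_in^2)) / (A_out - A_in)`.
#' When the areas are equal (flat sheet) this reduces to the identity
#' `rho = alpha`; the endpoints 0 and 1 are always preserved.
#'
#' @param alpha numeric vector/array of laminar Laplace fractions in `[0,1]`
#' @param inner_area,outer_area positive areas (mm^2), scalar or per-element
#' @return equivolumetric fractions, same shape as `alpha`
#' @export
equivolume_transform <- function(alpha, inner_area, outer_area) {
  if (any(inner_area <= 0, na.rm = TRUE) || any(outer_area <= 0, na.rm = TRUE))
    stop("surface areas must be positive")
  a_in <- inner_area; a_out <- outer_area
  rho <- alpha
  dif <- a_out - a_in
  flat <- abs(dif) < 1e-9 * a_in
  num <- -a_in + sqrt(alpha * a_out^2 + (1 - alpha) * a_in^2)
  idx <- !flat & !is.na(alpha)
  if (length(dif) == 1L) {
    if (!flat) rho <- num / dif
  } else {
    rho[idx] <- (num / dif)[idx]
  }
  rho
}

# inverse: alpha from rho (used for the bijection property)
equivolume_inverse <- function(rho, inner_area, outer_area) {
  a_in <- inner_area; a_out <- outer_area
  dif <- a_out - a_in
  flat <- abs(dif) < 1e-9 * a_in
  r <- a_in + rho * dif
  alpha <- (r^2 - a_in^2) / (a_out^2 - a_in^2)
  if (length(dif) == 1L) { if (flat) alpha <- rho } else alpha[flat] <- rho[flat]
  alpha
}

#' Coordinate fields container
#'
#' @param ap,pd,io numeric 3D arrays in `[0,1]` on `domain_mask`, NaN outside
#' @param domain_mask logical 3D array
#' @param io_mode `"laplace"` or `"equivolume"`
#' @return object of class `coord_fields`
#' @export
coord_fields <- function(ap, pd, io, domain_mask,
                         io_mode = c("equivolume", "laplace")) {
  io_mode <- match.arg(io_mode)
  structure(list(ap = ap, pd = pd, io = io, domain_mask = domain_mask,
                 io_mode = io_mode), class = "coord_fields")
}

#' @export
print.coord_fields <- function(x, ...) {
  cat("<coord_fields> ", sum(x$domain_mask), " domain voxels, io_mode=",
      x$io_mode, "\n", sep = "")
  invisible(x)
}

# per-column inner/outer areas on a coarse unfolded (AP,PD) grid, from the
# native positions of the io=0 and io=1 level sets (moving-least-squares
# evaluation of the scattered GM samples)
column_areas <- function(lm, ap, pd, io, spec, grid = c(64L, 32L)) {
  gm <- as.vector(lm$data == lm$label_scheme["GM"])
  sites_unit <- cbind(ap[gm], pd[gm], io[gm])
  sites <- scale_to_unfolded(sites_unit, spec)
  world <- voxel_to_world(lm$affine, voxel_grid(dim(lm$data))[gm, , drop = FALSE])
  u <- rep(seq(0, 1, length.out = grid[1]), times = grid[2])
  v <- rep(seq(0, 1, length.out = grid[2]), each = grid[1])
  cell <- max(mean(lm$voxel_size), (prod(apply(sites, 2, function(s) diff(range(s)))) /
                                      nrow(sites))^(1/3) * 2)
  areas <- lapply(c(0, 1), function(level) {
    q <- scale_to_unfolded(cbind(u, v, level), spec)
    nat <- cpp_mls_interp(sites, world, q, 16L, cell)
    mesh <- make_grid_mesh(grid[1], grid[2], io_level = level, spec = spec)
    mesh$vertices <- nat
    matrix(vertex_area(mesh)$values, grid[1], grid[2])
  })
  names(areas) <- c("inner", "outer")
  areas
}

#' Compute AP, PD and IO coordinate fields for a labelmap
#'
#' Solves Laplace's equation over hippocampal grey matter for the three
#' intrinsic axes: anterior-posterior (HATA source to IndGris sink),
#' proximal-distal (MTLc to DG granule layer), and inner-outer (SRLM, plus
#' cysts by default, to the outer boundary).  The IO Laplace field is then
#' replaced by the equivolumetric depth unless `io_mode = "laplace"`.
#'
#' @param lm a validated [tissue_labelmap()]
#' @param io_mode `"equivolume"` (default) or `"laplace"` (raw Laplace IO)
#' @param io_outer `"union"` (pial plus background, default) or `"pial"`:
#'   what counts as the outer laminar boundary
#' @param cyst_inner treat cyst voxels as part of the inner boundary set
#'   together with SRLM (default TRUE)
#' @param tol,max_iter,connectivity,omega solver controls, see [solve_laplace()]
#' @param spec unfolded-space spec used for the equivolumetric column areas
#' @param area_grid coarse (AP, PD) grid for per-column surface areas
#' @return a [coord_fields()] object over the GM domain
#' @export
compute_coord_fields <- function(lm, io_mode = c("equivolume", "laplace"),
                                 io_outer = c("union", "pial"),
                                 cyst_inner = TRUE,
                                 tol = 1e-5, max_iter = 10000L,
                                 connectivity = 6L, omega = 1.8,
                                 spec = unfolded_space_spec("hipp"),
                                 area_grid = c(64L, 32L)) {
  io_mode <- match.arg(io_mode)
  io_outer <- match.arg(io_outer)
  gm <- label_mask(lm, "GM")
  solve1 <- function(src, snk)
    solve_laplace(gm, src, snk, tol = tol, max_iter = max_iter,
                  connectivity = connectivity, omega = omega)
  ap <- solve1(label_mask(lm, "HATA"), label_mask(lm, "IndGris"))
  pd <- solve1(label_mask(lm, "MTLc"), label_mask(lm, "DGgranule"))
  inner <- label_mask(lm, "SRLM")
  if (cyst_inner) inner <- inner | label_mask(lm, "cyst")
  outer <- label_mask(lm, "pial")
  if (io_outer == "union") outer <- outer | (lm$data == lm$label_scheme["background"])
  io <- solve1(inner, outer)
  if (io_mode == "equivolume") {
    areas <- column_areas(lm, ap, pd, io, spec, grid = area_grid)
    gmv <- as.vector(gm)
    # bilinear lookup of per-column areas at each voxel's (AP, PD)
    pix <- cbind(ap[gmv] * (area_grid[1] - 1), pd[gmv] * (area_grid[2] - 1), 0)
    a_in <- cpp_trilinear(as.vector(areas$inner), c(area_grid, 1L), pix)
    a_out <- cpp_trilinear(as.vector(areas$outer), c(area_grid, 1L), pix)
    bad <- !is.finite(a_in) | !is.finite(a_out) | a_in <= 0 | a_out <= 0
    a_in[bad] <- 1; a_out[bad] <- 1  # identity fallback where areas undefined
    iov <- io
    iov[gmv] <- equivolume_transform(io[gmv], a_in, a_out)
    io <- iov
  }
  coord_fields(ap, pd, io, gm, io_mode = io_mode)
}

#' Write coordinate fields as NIfTI volumes
#'
#' Saves three float32 volumes on the input grid with suffixes
#' `_coords-AP`, `_coords-PD`, `_coords-IO`.
#'
#' @param fields a [coord_fields()]
#' @param lm the source [tissue_labelmap()] (for the affine)
#' @param prefix output path prefix
#' @return paths written, invisibly
#' @export
write_coord_fields <- function(fields, lm, prefix) {
  paths <- character(3)
  for (i in seq_along(c("AP", "PD", "IO"))) {
    ax <- c("AP", "PD", "IO")[i]
    arr <- fields[[tolower(ax)]]
    arr[!is.finite(arr)] <- 0
    paths[i] <- paste0(prefix, "_coords-", ax, ".nii.gz")
    write_nifti_volume(arr, paths[i], affine = lm$affine, datatype = "float")
  }
  invisible(paths)
}
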