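#' Octree hexahedral mesh from a binary segmentation
#'
#' Generates a uniform axis-aligned hexahedral mesh covering a binary mask:
#' the mask's voxel-boundary bounding box is subdivided into the coarsest
#' uniform grid whose edge lengths do not exceed `max_edge` (one uniform
#' octree refinement level), and every cell containing at least
#' `min_voxels` masked voxel centres is kept as an element.
#'
#' @param mask a [vol3d()] whose data is logical/0-1; non-empty.
#' @param max_edge maximum element edge length, mm; must exceed the largest
#'   voxel spacing.
#' @param min_voxels minimum number of masked voxel centres a cell must
#'   contain to be kept (default 1).
#' @return object of class `hex_mesh` with fields `nodes` (`n x 3`, world
#'   mm), `elems` (`ne x 8`, 1-based connectivity in VTK hexahedron order),
#'   `h` (edge lengths, mm), `origin`, `grid_dim` (cells per axis),
#'   `cell_ijk` (`ne x 3`, 0-based cell indices) and `elem_lookup`
#'   (dense array mapping cell index to element id).
#' @export
build_octree_hex_mesh <- function(mask, max_edge = 5, min_voxels = 1L) {
  stopifnot(inherits(mask, "vol3d"))
  m <- mask$data > 0
  if (!any(m)) stop("empty mask: nothing to mesh")
  if (max_edge <= max(mask$spacing))
    stop("max_edge must exceed the largest voxel spacing")
  idx <- which(m, arr.ind = TRUE) - 1L      # 0-based voxel indices
  lo_vox <- apply(idx, 2, min)
  hi_vox <- apply(idx, 2, max)
  # voxel-boundary bounding box in world mm
  lo <- mask$origin + lo_vox * mask$spacing - mask$spacing / 2
  hi <- mask$origin + hi_vox * mask$spacing + mask$spacing / 2
  ext <- hi - lo
  ncell <- pmax(1L, as.integer(ceiling(ext / max_edge - 1e-9)))
  h <- ext / ncell
  # count masked voxel centres per cell
  ctr <- sweep(sweep(idx, 2, mask$spacing, "*"), 2, mask$origin, "+")
  ci <- pmin(pmax(floor(sweep(sweep(ctr, 2, lo, "-"), 2, h, "/")), 0),
             matrix(rep(ncell - 1L, each = nrow(ctr)), ncol = 3))
  lin <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3]) + 1
  counts <- tabulate(lin, nbins = prod(ncell))
  keep <- which(counts >= min_voxels)
  if (length(keep) == 0) stop("no cell contains enough masked voxels")
  kk <- arrayInd(keep, ncell) - 1L          # 0-based cell ijk
  # global node grid (ncell+1 per axis); build node ids for used nodes only
  np <- ncell + 1L
  node_lin_of <- function(i, j, k) i + np[1] * (j + np[2] * k) + 1
  # 8 corners in VTK order
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  conn_lin <- matrix(0L, nrow(kk), 8)
  for (a in 1:8)
    conn_lin[, a] <- node_lin_of(kk[, 1] + corner[a, 1],
                                 kk[, 2] + corner[a, 2],
                                 kk[, 3] + corner[a, 3])
  used <- sort(unique(as.vector(conn_lin)))
  remap <- integer(prod(np))
  remap[used] <- seq_along(used)
  elems <- matrix(remap[conn_lin], ncol = 8)
  ug <- arrayInd(used, np) - 1L
  nodes <- cbind(lo[1] + ug[, 1] * h[1], lo[2] + ug[, 2] * h[2],
                 lo[3] + ug[, 3] * h[3])
  lookup <- array(0L, dim = ncell)
  lookup[keep] <- seq_along(keep)
  structure(list(nodes = nodes, elems = elems, h = h, origin = lo,
                 grid_dim = ncell, cell_ijk = kk, elem_lookup = lookup),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hexahedral elements, edge %s mm\n",
              nrow(x$nodes), nrow(x$elems),
              paste(signif(x$h, 4), collapse = "x")))
  invisible(x)
}

#' Locate the elements containing world points
#'
#' Uniform-grid lookup; points outside any kept element get `NA`.
#'
#' @param mesh a `hex_mesh`.
#' @param pts `n x 3` world coordinates, mm.
#' @return integer vector of element ids (NA outside the mesh).
#' @export
locate_elements <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 3L)
  u <- sweep(sweep(pts, 2, mesh$origin, "-"), 2, mesh$h, "/")
  ci <- floor(u)
  # points exactly on the upper boundary belong to the last cell
  for (a in 1:3)
    ci[, a] <- ifelse(u[, a] == mesh$grid_dim[a], mesh$grid_dim[a] - 1, ci[, a])
  ok <- ci[, 1] >= 0 & ci[, 1] < mesh$grid_dim[1] &
        ci[, 2] >= 0 & ci[, 2] < mesh$grid_dim[2] &
        ci[, 3] >= 0 & ci[, 3] < mesh$grid_dim[3]
  out <- rep(NA_integer_, nrow(pts))
  if (any(ok)) {
    lin <- ci[ok, 1] + mesh$grid_dim[1] * (ci[ok, 2] + mesh$grid_dim[2] * ci[ok, 3]) + 1
    e <- mesh$elem_lookup[lin]
    e[e == 0L] <- NA_integer_
    out[ok] <- e
  }
  out
}

# trilinear shape functions on the bi-unit cube, VTK node order
hex_ref_coords <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))

#' Trilinear hexahedral shape functions
#'
#' Values and local-coordinate gradients of the 8 nodal shape functions at
#' local points `xi` in the bi-unit cube.
#'
#' @param xi `n x 3` local coordinates in `[-1, 1]^3`.
#' @return list with `N` (`n x 8`) and `dN` (`n x 8 x 3`).
#' @export
hex_shape <- function(xi) {
  xi <- matrix(xi, ncol = 3L)
  n <- nrow(xi)
  N <- matrix(0, n, 8)
  dN <- array(0, c(n, 8, 3))
  for (a in 1:8) {
    ra <- hex_ref_coords[a, ]
    tx <- 1 + xi[, 1] * ra[1]; ty <- 1 + xi[, 2] * ra[2]; tz <- 1 + xi[, 3] * ra[3]
    N[, a] <- tx * ty * tz / 8
    dN[, a, 1] <- ra[1] * ty * tz / 8
    dN[, a, 2] <- ra[2] * tx * tz / 8
    dN[, a, 3] <- ra[3] * tx * ty / 8
  }
  list(N = N, dN = dN)
}

# local coordinates of world points within their (axis-aligned) element
hex_local_coords <- function(mesh, elem_ids, pts) {
  pts <- matrix(pts, ncol = 3L)
  n0 <- mesh$nodes[mesh$elems[elem_ids, 1], , drop = FALSE]
  2 * sweep(pts - n0, 2, mesh$h, "/") - 1
}
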