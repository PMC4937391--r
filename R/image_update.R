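#' Dense per-voxel displacement field from a solved XFEM field
#'
#' Evaluates the discontinuous displacement field at every voxel centre of
#' the image grid; each voxel is evaluated on its own side of the crack (the
#' sign of its `phi` selects the Heaviside branch), so the voxel field jumps
#' across the crack exactly as the mesh field does. Voxels outside the
#' meshed domain get zero displacement.
#'
#' @param field a `displacement_field` from [solve_retraction()].
#' @param grid a [vol3d()] defining the voxel grid.
#' @return 4D array `dim(grid) x 3` of displacements, mm.
#' @export
dense_displacement_field <- function(field, grid) {
  pts <- voxel_centers(grid)
  u <- displacement_at(field$enr, field$dofs, pts, outside = "zero")
  array(u, dim = c(dim(grid$data), 3))
}

#' Crack-aware backward warp of the pre-retraction image
#'
#' Produces the predicted post-retraction image by back-interpolation: for
#' every output voxel `y` the preimage `x` with `x + u(x) = y` is found by
#' fixed-point iteration on the forward displacement field, and the source
#' image is sampled at `x` with trilinear weights restricted to source
#' voxels on the same side of the crack as `x`. Voxels whose preimage falls
#' inside the opened crack (no consistent preimage) receive the background
#' intensity.
#'
#' @param pre a [vol3d()] pre-retraction image.
#' @param field a `displacement_field`, or a 4D array displacement field on
#'   the grid of `pre` (then `enr` must be given for crack awareness).
#' @param enr the `enriched_hex_mesh` (taken from `field` when omitted).
#' @param background intensity for gap / out-of-domain voxels (default:
#'   image minimum).
#' @param iterations fixed-point iterations for the field inversion.
#' @param gap_tol residual forward-map mismatch (mm) above which an output
#'   voxel is declared inside the opened gap.
#' @return a [vol3d()] predicted post-retraction image.
#' @export
warp_image_backward <- function(pre, field, enr = NULL,
                                background = min(pre$data),
                                iterations = 5L, gap_tol = 1.0) {
  if (inherits(field, "displacement_field")) {
    enr <- field$enr
    ufun <- function(p) displacement_at(enr, field$dofs, p, outside = "zero")
  } else {
    darr <- field
    if (!identical(dim(darr)[1:3], dim(pre$data)))
      stop("displacement field grid does not match the image")
    uvol <- lapply(1:3, function(a)
      vol3d(array(darr[, , , a], dim(pre$data)), pre$spacing, pre$origin))
    ufun <- function(p) cbind(sample_volume(uvol[[1]], p, 0),
                              sample_volume(uvol[[2]], p, 0),
                              sample_volume(uvol[[3]], p, 0))
  }
  y <- voxel_centers(pre)
  x <- y
  for (k in seq_len(iterations)) x <- y - ufun(x)
  # forward-consistency: preimages that do not map back onto y lie in the gap
  mismatch <- sqrt(rowSums((x + ufun(x) - y)^2))
  gap <- mismatch > gap_tol
  vals <- sample_volume_crack_aware(pre, x, enr, background)
  vals[gap] <- background
  vol3d(array(vals, dim(pre$data)), pre$spacing, pre$origin)
}

# trilinear sampling with weights masked to the crack side of the sample
# point; neighbours separated from x by the crack (phi sign change with
# psi < 0 on either end) get zero weight. Falls back to background when all
# neighbour weights vanish.
sample_volume_crack_aware <- function(vol, pts, enr = NULL,
                                      background = min(vol$data)) {
  crack <- if (!is.null(enr)) enr$crack else NULL
  if (is.null(crack)) return(sample_volume(vol, pts, background))
  pts <- matrix(pts, ncol = 3L)
  d <- dim(vol$data)
  ls_x <- level_set_pair(crack, pts)
  side_x <- heaviside(ls_x$phi)
  cracked_x <- ls_x$psi < 0
  u <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
  i0 <- floor(u)
  f <- u - i0
  acc <- numeric(nrow(pts)); wacc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    wt <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
          (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
          (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] & wt > 0
    if (!any(ok)) next
    nb <- cbind(vol$origin[1] + ii * vol$spacing[1],
                vol$origin[2] + jj * vol$spacing[2],
                vol$origin[3] + kk * vol$spacing[3])
    ls_n <- level_set_pair(crack, nb[ok, , drop = FALSE])
    blocked <- heaviside(ls_n$phi) != side_x[ok] &
               (cracked_x[ok] | ls_n$psi < 0)
    ok2 <- ok
    ok2[ok][blocked] <- FALSE
    if (any(ok2)) {
      lin <- ii[ok2] + d[1] * (jj[ok2] + d[2] * kk[ok2]) + 1
      acc[ok2] <- acc[ok2] + wt[ok2] * vol$data[lin]
      wacc[ok2] <- wacc[ok2] + wt[ok2]
    }
  }
  out <- rep(as.numeric(background), nrow(pts))
  use <- wacc > 1e-12
  out[use] <- acc[use] / wacc[use]
  out
}

#' Export a dense displacement field as a 4D NIfTI
#'
#' @param darr 4D array (`nx x ny x nz x 3`), mm.
#' @param grid the [vol3d()] grid it lives on.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_displacement_nifti <- function(darr, grid, path) {
  img <- RNifti::asNifti(darr)
  RNifti::pixdim(img) <- c(grid$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
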