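#' Axis-aligned scalar volume image
#'
#' Lightweight container for a 3D scalar image on an axis-aligned world grid:
#' voxel indices are 0-based and voxel-centred, so the world position of
#' voxel `(i, j, k)` is `origin + c(i, j, k) * spacing` (mm).
#'
#' @param data 3D numeric/logical array.
#' @param spacing voxel spacing, mm (length 3, all `> 0`).
#' @param origin world position of voxel (0,0,0), mm (length 3).
#' @return object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' World coordinates of all voxel centres
#'
#' @param vol a [vol3d()].
#' @return `n x 3` matrix of world coordinates (mm), in array storage order.
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers around RNifti. Only axis-aligned affines are supported: the
#' image affine is reduced to spacing + origin on read and reconstructed on
#' write.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [read_volume()] returns a [vol3d()]; [write_volume()] returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  sp <- hdr$pixdim[2:4]
  aff <- RNifti::xform(img)
  # accept axis-aligned orientations only
  orig <- aff[1:3, 4]
  vol3d(array(as.numeric(img), dim = dim(img)[1:3]),
        spacing = abs(sp), origin = as.numeric(orig))
}

#' @param vol a [vol3d()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Trilinear sampling of a volume at world points
#'
#' @param vol a [vol3d()].
#' @param pts `n x 3` world coordinates, mm.
#' @param background value returned outside the volume.
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, pts, background = min(vol$data)) {
  pts <- matrix(pts, ncol = 3L)
  d <- dim(vol$data)
  # continuous 0-based voxel coordinates
  u <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
  i0 <- floor(u)
  f <- u - i0
  out <- rep(as.numeric(background), nrow(pts))
  acc <- numeric(nrow(pts))
  wacc <- numeric(nrow(pts))
  inside_any <- rep(FALSE, nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    wt <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
          (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
          (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] & wt > 0
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      acc[ok] <- acc[ok] + wt[ok] * vol$data[lin]
      wacc[ok] <- wacc[ok] + wt[ok]
      inside_any <- inside_any | ok
    }
  }
  use <- inside_any & wacc > 0
  out[use] <- acc[use] / wacc[use]
  out
}
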