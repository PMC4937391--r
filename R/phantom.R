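#' Phantom configuration
#'
#' Parameters of the deterministic synthetic phantom that stands in for the
#' CT/LRS data of a retraction experiment: an ellipsoidal brain-like mask, a
#' planar mid-line crack, V-shaped retractor blades (14 mm wide, 2.9 mm
#' thick) opened a few mm, and 11-20 embedded bead landmarks distributed
#' over three lobe-like regions.
#'
#' @param semi_axes ellipsoid semi-axes, mm.
#' @param spacing voxel spacing of the phantom images, mm.
#' @param crack_point,crack_normal crack plane pose (world mm / direction).
#' @param retractor_width blade width, mm (extent along the crack plane).
#' @param retractor_thickness blade thickness, mm.
#' @param retractor_depth insertion depth below the top surface, mm.
#' @param retractor_center in-plane centre of the blade along y, mm.
#' @param openings maximum face displacements, mm: positive side, then
#'   negative side (magnitudes; the V-shape tapers linearly to zero at the
#'   blade tip).
#' @param n_beads number of bead landmarks (>= 1; study convention 11-20).
#' @param cloud_spacing grid spacing of the synthetic retractor-surface
#'   point clouds, mm.
#' @param cloud_bow parabolic out-of-plane sag of the scanned blade surface
#'   across its width, mm (a real scanned blade surface is never perfectly
#'   flat; a genuinely 3D cloud also keeps affine registration well-posed).
#' @param cloud_jitter half-width of the uniform in-plane jitter applied to
#'   the cloud sample positions, mm (scanner samples are not lattice
#'   points; a perfectly regular grid would also alias the point-set
#'   correspondence).
#' @param seed RNG seed; all phantom randomness flows from it.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(semi_axes = c(40, 32, 28), spacing = c(1.5, 1.5, 1.5),
                           crack_point = c(1.3, 5, 0),
                           crack_normal = c(1, 0, 0),
                           retractor_width = 14, retractor_thickness = 2.9,
                           retractor_depth = 20, retractor_center = 5,
                           openings = c(5.4, 2.8), n_beads = 14L,
                           cloud_spacing = 1.2, cloud_bow = 1.0,
                           cloud_jitter = 0.4, seed = 1L) {
  if (any(openings < 0)) stop("openings must be non-negative")
  if (n_beads < 1) stop("need at least one bead")
  structure(list(semi_axes = semi_axes, spacing = spacing,
                 crack_point = crack_point,
                 crack_normal = crack_normal / sqrt(sum(crack_normal^2)),
                 retractor_width = retractor_width,
                 retractor_thickness = retractor_thickness,
                 retractor_depth = retractor_depth,
                 retractor_center = retractor_center,
                 openings = openings, n_beads = as.integer(n_beads),
                 cloud_spacing = cloud_spacing, cloud_bow = cloud_bow,
                 cloud_jitter = cloud_jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

ellipsoid_value <- function(pts, semi_axes) {
  pts <- matrix(pts, ncol = 3L)
  rowSums(sweep(pts, 2, semi_axes, "/")^2)
}

#' Generate the synthetic retraction phantom
#'
#' Produces every input the simulation pipeline needs: the binary ellipsoid
#' mask, a CT-like intensity image (smooth radial gradient plus bright
#' 1.5 mm bead spheres), the planar through-going crack, pre/post retractor
#' point clouds for both crack faces (post = pre displaced by the V-shaped
#' opening), and the pre-retraction bead landmark coordinates. Bitwise
#' reproducible for a given seed.
#'
#' @param config a [phantom_config()].
#' @return list with `mask`, `intensity` ([vol3d()]s), `crack`
#'   ([crack_plane()]), `clouds` (list per face: `face`, `pre`, `post`
#'   [point_cloud()]s, `displacements`), `landmarks` ([landmark_set()], pre
#'   coordinates), `taper` (the opening profile function of z), and
#'   `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  set.seed(config$seed)
  sa <- config$semi_axes
  sp <- config$spacing
  margin <- 3
  lo <- -sa - margin
  dims <- ceiling((2 * sa + 2 * margin) / sp) + 1
  grid <- vol3d(array(0, dims), spacing = sp, origin = lo)
  ctr <- voxel_centers(grid)
  inside <- ellipsoid_value(ctr, sa) <= 1
  mask <- vol3d(array(as.numeric(inside), dims), sp, lo)
  # crack
  crack <- crack_plane(config$crack_point, config$crack_normal, through = TRUE)
  # retractor geometry: blade inserted from the top (+z), in-plane axis y
  z_top <- sa[3] * 0.98
  z_tip <- z_top - config$retractor_depth
  y0 <- config$retractor_center - config$retractor_width / 2
  y1 <- config$retractor_center + config$retractor_width / 2
  taper <- function(z) pmin(pmax((z - z_tip) / (z_top - z_tip), 0), 1)
  gy <- seq(y0, y1, by = config$cloud_spacing)
  gz <- seq(z_tip, z_top, by = config$cloud_spacing)
  gpts <- as.matrix(expand.grid(y = gy, z = gz))
  gpts <- gpts + matrix(runif(length(gpts), -config$cloud_jitter,
                              config$cloud_jitter), ncol = 2)
  gpts[, 2] <- pmin(pmax(gpts[, 2], z_tip), z_top)
  # scanned blade surfaces are not perfectly flat: parabolic bow across the
  # blade width (also makes the cloud genuinely 3D for affine registration)
  bow <- config$cloud_bow *
    (1 - ((gpts[, 1] - config$retractor_center) / (config$retractor_width / 2))^2)
  base <- cbind(config$crack_point[1] + bow, gpts[, 1], gpts[, 2])
  keep <- ellipsoid_value(base, sa * 0.99) <= 1
  base <- base[keep, , drop = FALSE]
  n <- crack$normal
  clouds <- lapply(c(1, -1), function(face) {
    mag <- if (face > 0) config$openings[1] else config$openings[2]
    disp <- outer(taper(base[, 3]), face * mag * n)
    pre <- point_cloud(base, matrix(face * n, nrow(base), 3, byrow = TRUE),
                       frame = "image")
    post <- point_cloud(base + disp, pre$normals, frame = "image")
    list(face = face, pre = pre, post = post, displacements = disp)
  })
  # beads in three lobe-like clusters (frontal / parietal / occipital),
  # uniform within each cluster box intersected with a shrunken ellipsoid
  boxes <- list(frontal = cbind(c(-20, 20), c(10, 24), c(2, 18)),
                parietal = cbind(c(-20, 20), c(-8, 8), c(4, 20)),
                occipital = cbind(c(-20, 20), c(-24, -10), c(2, 18)))
  nb <- config$n_beads
  per <- rep(floor(nb / 3), 3)
  per[seq_len(nb - sum(per))] <- per[seq_len(nb - sum(per))] + 1
  beads <- NULL
  for (ci in 1:3) {
    bx <- boxes[[ci]]
    got <- 0; tries <- 0
    while (got < per[ci]) {
      tries <- tries + 1
      if (tries > 10000)
        stop("could not place beads inside the mask (cluster ",
             names(boxes)[ci], ")")
      p <- c(runif(1, bx[1, 1], bx[2, 1]), runif(1, bx[1, 2], bx[2, 2]),
             runif(1, bx[1, 3], bx[2, 3]))
      # inside a shrunken ellipsoid and at least 1.5 mm off the crack plane
      if (ellipsoid_value(p, sa * 0.85) <= 1 &&
          abs(sum((p - crack$point) * crack$normal)) > 1.5) {
        beads <- rbind(beads, p)
        got <- got + 1
      }
    }
  }
  rownames(beads) <- NULL
  lm <- landmark_set(seq_len(nb), beads)
  # CT-like intensity: soft radial gradient + bright 1.5 mm bead spheres
  re <- ellipsoid_value(ctr, sa)
  intens <- ifelse(inside, 40 + 20 * (1 - re), 0)
  for (b in seq_len(nb)) {
    d2 <- rowSums(sweep(ctr, 2, beads[b, ])^2)
    intens[d2 <= 1.5^2] <- 3000
  }
  intensity <- vol3d(array(intens, dims), sp, lo)
  list(mask = mask, intensity = intensity, crack = crack, clouds = clouds,
       landmarks = lm, taper = taper, config = config)
}

#' Boundary conditions for the phantom (or any tracked retractor clouds)
#'
#' Runs the surface-tracking chain on the phantom's clouds: per crack face,
#' register the pre cloud onto the post cloud with affine coherent point
#' drift, transfer the recovered per-point displacements to the
#' Heaviside-enriched nodes of the elements touched by the cloud
#' (inverse-distance weighting), and keep the nodes covered on both faces.
#' Combined with the zero-displacement brain-stem band this yields the
#' [bc_set()] for [solve_retraction()].
#'
#' @param phantom output of [generate_phantom()].
#' @param enr an `enriched_hex_mesh` built on the phantom mask and crack.
#' @param stem_fraction fraction of the mesh height (from the bottom) whose
#'   nodes form the zero-displacement brain-stem band.
#' @param radius influence radius for the node transfer, mm (default: the
#'   element size).
#' @param use_cpd register clouds with CPD (`TRUE`) or use the phantom's
#'   known per-point displacements directly (`FALSE`).
#' @return a [bc_set()].
#' @export
phantom_bcs <- function(phantom, enr, stem_fraction = 0.18,
                        radius = max(enr$mesh$h), use_cpd = TRUE) {
  mesh <- enr$mesh
  zlo <- min(mesh$nodes[, 3])
  zhi <- max(mesh$nodes[, 3])
  stem <- which(mesh$nodes[, 3] <= zlo + stem_fraction * (zhi - zlo))
  rows <- NULL
  covered <- list()
  for (cl in phantom$clouds) {
    disp <- if (use_cpd) {
      register_point_sets(cl$pre, cl$post, mode = "affine")$displacements
    } else cl$displacements
    eid <- locate_elements(mesh, cl$pre$points)
    touched <- unique(eid[!is.na(eid)])
    jn <- intersect(unique(as.vector(mesh$elems[touched, , drop = FALSE])),
                    enr$J)
    # keep nodes actually covered by the tracked cloud
    jc <- mesh$nodes[jn, , drop = FALSE]
    dmin <- vapply(seq_along(jn), function(i)
      min(sqrt(colSums((t(cl$pre$points) - jc[i, ])^2))), numeric(1))
    jn <- jn[dmin <= radius]
    jn <- setdiff(jn, stem)
    covered[[as.character(cl$face)]] <- jn
    rows <- rbind(rows, map_displacements_to_nodes(
      cl$pre, disp, jn, mesh$nodes[jn, , drop = FALSE], cl$face, radius))
  }
  both <- intersect(covered[["1"]], covered[["-1"]])
  rows <- rows[rows$node %in% both, ]
  bc_set(fixed_nodes = stem, crack_face_bcs = rows)
}

#' Ground-truth landmark displacements from a reference solve
#'
#' Advects the phantom's bead landmarks with a (fine-mesh) reference
#' displacement field; the advected positions play the role of the measured
#' post-retraction landmark coordinates when scoring a coarser prediction.
#'
#' @param phantom output of [generate_phantom()].
#' @param field a converged `displacement_field` (the reference solve).
#' @return the phantom [landmark_set()] with `measured` coordinates filled.
#' @export
ground_truth_displacements <- function(phantom, field) {
  pre <- lm_coords(phantom$landmarks, "pre")
  u <- displacement_at(field$enr, field$dofs, pre, outside = "error")
  landmark_set(phantom$landmarks$id, pre, measured = pre + u)
}
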