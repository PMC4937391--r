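#' Point cloud container
#'
#' @param points `n x 3` matrix of coordinates, mm.
#' @param normals optional `n x 3` matrix of unit normals.
#' @param frame optional character tag naming the coordinate frame.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, frame = "image") {
  points <- matrix(points, ncol = 3L)
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (!is.null(normals)) {
    normals <- matrix(normals, ncol = 3L)
    stopifnot(nrow(normals) == nrow(points))
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) normals <- normals / len
  }
  structure(list(points = points, normals = normals, frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s, frame '%s'\n", nrow(x$points),
              if (is.null(x$normals)) "" else " with normals", x$frame))
  invisible(x)
}

#' Extrude a retractor surface cloud along its normals
#'
#' Translates every point by the retractor blade thickness along its surface
#' normal — the step that converts the scanned inner retractor surface into
#' the post-retraction tissue-contact surface (blade thickness 2.9 mm by
#' default).
#'
#' @param cloud a [point_cloud()] with normals.
#' @param thickness extrusion distance, mm (`>= 0`).
#' @return the extruded [point_cloud()].
#' @export
extrude_retractor_surface <- function(cloud, thickness = 2.9) {
  if (is.null(cloud$normals)) stop("cloud has no normals; cannot extrude")
  if (thickness < 0) stop("thickness must be non-negative")
  point_cloud(cloud$points + thickness * cloud$normals, cloud$normals,
              cloud$frame)
}

#' Coherent point drift registration
#'
#' EM point-set registration of `source` onto `target` (Myronenko &
#' Song's coherent point drift) in `rigid` or `affine` mode, with uniform
#' outlier weight `w`. Per-source-point displacements are the posterior-mean
#' matched target positions minus the source positions.
#'
#' @param source,target [point_cloud()]s (or bare `n x 3` matrices);
#'   at least 3 points each and non-degenerate in affine mode.
#' @param mode `"rigid"` (rotation + translation) or `"affine"`.
#' @param w uniform outlier weight in `[0, 1)`.
#' @param max_iter,tol EM iteration controls (change in sigma^2).
#' @return list with `transform` (4x4 affine matrix mapping source to
#'   target), `displacements` (`n x 3`, mm), `transformed` (moved source
#'   points), `sigma2` and `iterations`.
#' @export
register_point_sets <- function(source, target, mode = c("rigid", "affine"),
                                w = 0.1, max_iter = 100L, tol = 1e-8) {
  mode <- match.arg(mode)
  Y <- if (inherits(source, "point_cloud")) source$points else matrix(source, ncol = 3)
  X <- if (inherits(target, "point_cloud")) target$points else matrix(target, ncol = 3)
  M <- nrow(Y); N <- nrow(X); D <- 3
  if (M < 3 || N < 3) stop("need at least 3 points in each cloud")
  if (mode == "affine") {
    sv <- svd(sweep(Y, 2, colMeans(Y)))$d
    if (sv[3] < 1e-9 * max(sv[1], 1))
      stop("degenerate (coplanar/collinear) source cloud in affine mode")
  }
  # normalise: centre each cloud on its own mean, one common RMS scale
  # (keeps the EM annealing well-behaved; undone on output)
  Y0 <- Y; X0 <- X
  ym <- colMeans(Y); xm <- colMeans(X)
  scl <- sqrt((mean(rowSums(sweep(X, 2, xm)^2)) +
               mean(rowSums(sweep(Y, 2, ym)^2))) / 2)
  if (scl <= 0) scl <- 1
  Y <- sweep(Y, 2, ym) / scl
  X <- sweep(X, 2, xm) / scl
  TY <- Y
  R <- diag(3); B <- diag(3); tvec <- c(0, 0, 0)
  sigma2 <- sum(outer(rowSums(X^2), rep(1, M)) +
                outer(rep(1, N), rowSums(Y^2)) -
                2 * X %*% t(Y)) / (D * M * N)
  sigma2_scale <- sigma2              # initial (data-scale) variance
  sigma2_floor <- 1e-10 * sigma2_scale  # relative floor: a perfect match
  for (it in seq_len(max_iter)) {
    # E-step: posterior correspondence P (M x N)
    d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), rowSums(X^2)) -
          2 * TY %*% t(X)
    G <- exp(-d2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    denom <- colSums(G) + cst
    P <- sweep(G, 2, denom, "/")
    Np <- sum(P)
    P1 <- rowSums(P)            # M
    Pt1 <- colSums(P)           # N
    mu_x <- as.numeric(t(X) %*% Pt1) / Np
    mu_y <- as.numeric(t(Y) %*% P1) / Np
    Xh <- sweep(X, 2, mu_x); Yh <- sweep(Y, 2, mu_y)
    A <- t(Xh) %*% t(P) %*% Yh
    if (mode == "rigid") {
      sv <- svd(A)
      C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
      R <- sv$u %*% C %*% t(sv$v)
      tvec <- mu_x - as.numeric(R %*% mu_y)
      TY <- sweep(Y %*% t(R), 2, tvec, "+")
      # strict rigid (unit scale): the variance update keeps all three terms
      sigma2_new <- (sum(Pt1 * rowSums(Xh^2)) -
                     2 * sum(diag(t(A) %*% R)) +
                     sum(P1 * rowSums(Yh^2))) / (Np * D)
    } else {
      YPY <- t(Yh) %*% (P1 * Yh)
      B <- A %*% solve(YPY)
      tvec <- mu_x - as.numeric(B %*% mu_y)
      TY <- sweep(Y %*% t(B), 2, tvec, "+")
      sigma2_new <- (sum(Pt1 * rowSums(Xh^2)) -
                     sum(diag(t(A) %*% B))) / (Np * D)
    }
    if (!is.finite(sigma2_new) || sigma2_new <= sigma2_floor) {
      # variance has collapsed onto the data: converged
      sigma2 <- sigma2_floor
      break
    }
    if (abs(sigma2 - sigma2_new) < tol * sigma2) { sigma2 <- sigma2_new; break }
    sigma2 <- sigma2_new
  }
  # posterior-mean matched target position per source point (a floored
  # variance keeps the correspondence well-defined after full convergence)
  sigma2_match <- max(sigma2, 1e-6 * sigma2_scale)
  d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), rowSums(X^2)) -
        2 * TY %*% t(X)
  d2 <- pmax(d2, 0)
  G <- exp(-d2 / (2 * sigma2_match))
  cst <- (2 * pi * sigma2_match)^(D / 2) * w / (1 - w) * M / N
  P <- sweep(G, 2, colSums(G) + cst, "/")
  P1 <- rowSums(P)
  match_pos <- (P %*% X) / pmax(P1, 1e-300)
  # for points with negligible posterior mass fall back to the transform
  weak <- P1 < 1e-8
  match_pos[weak, ] <- TY[weak, ]
  # denormalise back to world coordinates
  L <- if (mode == "rigid") R else B
  tvec_w <- scl * tvec + xm - as.numeric(L %*% ym)
  match_w <- sweep(scl * match_pos, 2, xm, "+")
  TY_w <- sweep(scl * TY, 2, xm, "+")
  tf <- diag(4)
  tf[1:3, 1:3] <- L
  tf[1:3, 4] <- tvec_w
  list(transform = tf, displacements = match_w - Y0,
       transformed = TY_w, sigma2 = sigma2 * scl^2, iterations = it)
}

#' Transfer tracked surface displacements to crack-face nodes
#'
#' Inverse-distance-weighted average of the cloud-point displacements within
#' `radius` of each listed node, assigned to the given crack face.
#'
#' @param cloud a [point_cloud()] (pre-retraction positions).
#' @param displacements `n x 3` per-point displacement vectors, mm (e.g.
#'   from [register_point_sets()]).
#' @param nodes integer node ids to cover.
#' @param node_coords `length(nodes) x 3` node coordinates, mm.
#' @param face crack-face sign (+1/-1) these displacements belong to.
#' @param radius influence radius, mm (default: element-size scale of the
#'   spacing between cloud points).
#' @param power inverse-distance weighting exponent.
#' @return data.frame of [bc_set()] `crack_face_bcs` rows.
#' @export
map_displacements_to_nodes <- function(cloud, displacements, nodes,
                                       node_coords, face, radius,
                                       power = 1) {
  pts <- cloud$points
  if (nrow(pts) == 0) stop("empty cloud")
  displacements <- matrix(displacements, ncol = 3L)
  stopifnot(nrow(displacements) == nrow(pts))
  node_coords <- matrix(node_coords, ncol = 3L)
  out <- matrix(NA_real_, length(nodes), 3)
  uncovered <- integer(0)
  for (i in seq_along(nodes)) {
    d <- sqrt(colSums((t(pts) - node_coords[i, ])^2))
    sel <- which(d <= radius)
    if (length(sel) == 0) { uncovered <- c(uncovered, nodes[i]); next }
    if (any(d[sel] < 1e-12)) {
      out[i, ] <- displacements[sel[which.min(d[sel])], ]
    } else {
      wts <- 1 / d[sel]^power
      out[i, ] <- colSums(displacements[sel, , drop = FALSE] * wts) / sum(wts)
    }
  }
  if (length(uncovered) > 0)
    stop("no cloud point within radius of node(s): ",
         paste(uncovered, collapse = ", "))
  data.frame(node = as.integer(nodes), face = as.integer(face),
             ux = out[, 1], uy = out[, 2], uz = out[, 3])
}

#' Read / write point clouds (ASCII XYZ or PLY)
#'
#' Whitespace-delimited `x y z [nx ny nz]` files, or ASCII PLY with
#' `x y z [nx ny nz]` vertex properties.
#'
#' @param path file path; format chosen by extension (`.ply` vs anything
#'   else = XYZ).
#' @return [read_point_cloud()] returns a [point_cloud()];
#'   [write_point_cloud()] returns `path` invisibly.
#' @export
read_point_cloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    hend <- which(lines == "end_header")[1]
    if (is.na(hend)) stop("not an ASCII PLY file: ", path)
    nvert <- as.integer(sub("element vertex ", "",
                            grep("^element vertex ", lines, value = TRUE)[1]))
    props <- sub("^property \\S+ ", "",
                 grep("^property ", lines[seq_len(hend)], value = TRUE))
    dat <- read.table(text = lines[(hend + 1):(hend + nvert)])
    names(dat) <- props[seq_len(ncol(dat))]
    pts <- as.matrix(dat[, c("x", "y", "z")])
    nrm <- if (all(c("nx", "ny", "nz") %in% names(dat)))
      as.matrix(dat[, c("nx", "ny", "nz")]) else NULL
    return(point_cloud(pts, nrm))
  }
  dat <- as.matrix(read.table(path))
  point_cloud(dat[, 1:3], if (ncol(dat) >= 6) dat[, 4:6] else NULL)
}

#' @param cloud a [point_cloud()].
#' @rdname read_point_cloud
#' @export
write_point_cloud <- function(cloud, path) {
  dat <- cloud$points
  if (!is.null(cloud$normals)) dat <- cbind(dat, cloud$normals)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    props <- c("x", "y", "z", if (ncol(dat) == 6) c("nx", "ny", "nz"))
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(dat)),
             sprintf("property float %s", props), "end_header")
    body <- apply(dat, 1, function(r) paste(format(r, digits = 10),
                                            collapse = " "))
    writeLines(c(hdr, body), path)
  } else {
    write.table(dat, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
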