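test_that("point-cloud construction validates and normalises", {
  expect_error(point_cloud(matrix(c(1, Inf, 0), 1)), "finite")
  pc <- point_cloud(matrix(rnorm(30), 10), matrix(c(2, 0, 0), 10, 3,
                                                  byrow = TRUE))
  expect_equal(unname(pc$normals[1, ]), c(1, 0, 0))
})

test_that("retractor-surface extrusion moves points along their normals", {
  # planar cloud with +z normals: pure z shift by the blade thickness
  pts <- as.matrix(expand.grid(x = 1:5, y = 1:4))
  pts <- cbind(pts, 0)
  pc <- point_cloud(pts, matrix(c(0, 0, 1), nrow(pts), 3, byrow = TRUE))
  ex <- extrude_retractor_surface(pc, 2.9)
  expect_equal(ex$points[, 3], rep(2.9, nrow(pts)))
  expect_equal(ex$points[, 1:2], pc$points[, 1:2])
  expect_equal(extrude_retractor_surface(pc, 0)$points, pc$points)
  # spherical patch with radial normals: radii grow by the thickness
  set.seed(6)
  dirs <- matrix(rnorm(60), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sp <- point_cloud(5 * dirs, dirs)
  ex2 <- extrude_retractor_surface(sp, 2.9)
  expect_equal(sqrt(rowSums(ex2$points^2)), rep(7.9, 20))
  expect_error(extrude_retractor_surface(point_cloud(pts), 2.9), "normals")
})

test_that("CPD registration recovers identity and known rigid transforms", {
  set.seed(14)
  Y <- matrix(runif(450, -20, 20), ncol = 3)
  # identical clouds
  r0 <- register_point_sets(Y, Y, mode = "rigid")
  expect_lt(max(abs(r0$transform - diag(4))), 1e-6)
  expect_lt(max(abs(r0$displacements)), 1e-6)
  # 10 degree rotation about z plus translation
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tv <- c(1, 2, 3)
  X <- sweep(Y %*% t(R), 2, tv, "+")
  r <- register_point_sets(Y, X, mode = "rigid")
  expect_lt(max(abs(r$transform[1:3, 1:3] - R)), 1e-3)
  expect_lt(max(abs(r$transform[1:3, 4] - tv)), 1e-3)
  # rigid mode preserves pairwise distances of the transformed source
  expect_lt(max(abs(dist(r$transformed) - dist(Y))), 1e-9)
})

test_that("CPD recovers displacements under measurement noise", {
  set.seed(77)
  Y <- matrix(runif(1500, -25, 25), ncol = 3)   # 500 points
  th <- 6 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tv <- c(0.5, -1, 2)
  X <- sweep(Y %*% t(R), 2, tv, "+") + matrix(rnorm(1500, 0, 0.1), ncol = 3)
  r <- register_point_sets(Y, X, mode = "rigid")
  truth <- sweep(Y %*% t(R), 2, tv, "+") - Y
  rmse <- sqrt(mean(rowSums((r$displacements - truth)^2)))
  expect_lt(rmse, 0.2)
})

test_that("affine CPD handles affine fields and rejects degenerate clouds", {
  set.seed(15)
  Y <- matrix(runif(600, -10, 10), ncol = 3)
  B <- diag(3) + matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0, 0, 0.02, 0.04), 3)
  X <- sweep(Y %*% t(B), 2, c(1, -2, 0.5), "+")
  r <- register_point_sets(Y, X, mode = "affine")
  expect_lt(max(abs(r$transform[1:3, 1:3] - B)), 1e-3)
  flat <- cbind(matrix(runif(60, -5, 5), ncol = 2), 0)
  expect_error(register_point_sets(flat, flat + 1, mode = "affine"),
               "degenerate")
  expect_error(register_point_sets(Y[1:2, ], X[1:2, ]), "at least 3")
})

test_that("node transfer reproduces inverse-distance-weighted averages", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(5, 5, 5))
  disp <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  pc <- point_cloud(pts)
  # node coincident with a cloud point takes that displacement exactly
  b1 <- map_displacements_to_nodes(pc, disp, nodes = 7L,
                                   node_coords = rbind(c(2, 0, 0)),
                                   face = 1, radius = 3)
  expect_equal(as.numeric(b1[1, c("ux", "uy", "uz")]), c(0, 2, 0))
  # equidistant node averages the two displacements
  b2 <- map_displacements_to_nodes(pc, disp, nodes = 8L,
                                   node_coords = rbind(c(1, 0, 0)),
                                   face = -1, radius = 1.5)
  expect_equal(as.numeric(b2[1, c("ux", "uy", "uz")]), c(0.5, 1, 0))
  # random configuration against a brute-force re-computation
  set.seed(31)
  cl <- matrix(runif(90, 0, 10), ncol = 3)
  dp <- matrix(rnorm(90), ncol = 3)
  node <- c(4.8, 5.1, 5.3)
  b3 <- map_displacements_to_nodes(point_cloud(cl), dp, 1L, rbind(node),
                                   face = 1, radius = 4)
  dists <- sqrt(colSums((t(cl) - node)^2))
  sel <- dists <= 4
  w <- 1 / dists[sel]
  expect_equal(as.numeric(b3[1, c("ux", "uy", "uz")]),
               colSums(dp[sel, ] * w) / sum(w))
  expect_error(map_displacements_to_nodes(pc, disp, 9L,
                                          rbind(c(50, 50, 50)), 1, 2),
               "no cloud point")
})

test_that("point clouds round-trip through XYZ and PLY files", {
  set.seed(12)
  pts <- matrix(runif(45, -5, 5), ncol = 3)
  nrm <- matrix(rnorm(45), ncol = 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  pc <- point_cloud(pts, nrm)
  for (ext in c("xyz", "ply")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_point_cloud(pc, f)
    back <- read_point_cloud(f)
    expect_equal(back$points, unname(pc$points), tolerance = 1e-6)
    expect_equal(back$normals, unname(pc$normals), tolerance = 1e-6)
    unlink(f)
  }
})

test_that("tracked phantom BCs reproduce the known face displacements", {
  ph <- generate_phantom(phantom_config())
  mesh <- build_octree_hex_mesh(ph$mask, 5)
  enr <- classify_and_enrich(mesh, ph$crack)
  got <- phantom_bcs(ph, enr, use_cpd = TRUE)
  want <- phantom_bcs(ph, enr, use_cpd = FALSE)
  m <- merge(got$crack_face_bcs, want$crack_face_bcs, by = c("node", "face"))
  expect_equal(nrow(m), nrow(got$crack_face_bcs))
  err <- abs(as.matrix(m[, c("ux.x", "uy.x", "uz.x")]) -
             as.matrix(m[, c("ux.y", "uy.y", "uz.y")]))
  expect_lt(max(err), 0.1)   # within the registration tolerance
})
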