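# Solver-level correctness: patch test, FEM equivalence, crack kinematics,
# assembly consistency. All on the 512-element solid cube testbed.

test_that("zero DOFs give zero residual and rigid translation is stress-free", {
  mesh <- cube_mesh()
  enr <- classify_and_enrich(mesh, crack_plane(c(17.3, 0, 0), c(1, 0, 0),
                                               through = TRUE))
  id <- integration_data(enr, ogden_material())
  out0 <- assemble_system(id, numeric(id$ndof), dt = 0, tangent = FALSE)
  expect_equal(max(abs(out0$resid)), 0, tolerance = 1e-12)
  expect_equal(out0$energy, 0, tolerance = 1e-12)
  # rigid translation on all standard DOFs (enriched DOFs zero)
  d <- numeric(id$ndof)
  d[seq_len(3 * nrow(mesh$nodes))] <- rep(c(2, -1, 3), nrow(mesh$nodes))
  outT <- assemble_system(id, d, dt = 0, tangent = FALSE)
  expect_lt(max(abs(outT$resid)), 1e-8)
})

test_that("assembled tangent matches finite differences of the residual", {
  mk <- vol3d(array(1, c(10, 5, 5)), spacing = c(1, 1, 1),
              origin = c(0.5, 0.5, 0.5))
  mesh <- build_octree_hex_mesh(mk, 5)
  expect_equal(nrow(mesh$elems), 2L)
  enr <- classify_and_enrich(mesh, crack_plane(c(3.2, 0, 0), c(1, 0, 0),
                                               through = TRUE))
  id <- integration_data(enr, ogden_material())
  set.seed(42)
  d <- rnorm(id$ndof, 0, 0.05)
  st <- fresh_state(ogden_material(), id$n_gp)
  K <- as.matrix(assemble_system(id, d, st, dt = 1, tangent = TRUE)$K)
  h <- 1e-6
  for (j in sample(id$ndof, 25)) {
    dp <- d; dm <- d
    dp[j] <- dp[j] + h; dm[j] <- dm[j] - h
    fd <- (assemble_system(id, dp, st, dt = 1, tangent = FALSE)$resid -
           assemble_system(id, dm, st, dt = 1, tangent = FALSE)$resid) / (2 * h)
    expect_lt(max(abs(fd - K[, j])) / max(abs(K)), 1e-4)
  }
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-8)
})

test_that("homogeneous-deformation patch test is exact", {
  mesh <- cube_mesh()
  enr <- classify_and_enrich(mesh, NULL)
  id <- integration_data(enr, ogden_material())
  A <- matrix(c(0.03, 0.01, 0, 0.005, -0.02, 0.002, 0, 0.004, 0.01), 3, 3)
  f <- solve_retraction(id, affine_bcs(mesh, A), duration = 0, increments = 1,
                        rtol = 1e-12, atol = 1e-12, allow_no_fixed = TRUE)
  expect_lt(max(abs(nodal_displacements(f) - mesh$nodes %*% t(A))), 1e-8)
})

test_that("with an empty crack the XFEM solution equals plain FEM DOF-for-DOF", {
  mesh <- cube_mesh()
  A <- matrix(c(0.02, 0.008, 0, 0, -0.015, 0.003, 0.002, 0, 0.01), 3, 3)
  bcs <- affine_bcs(mesh, A)
  enr_fem <- classify_and_enrich(mesh, NULL)
  enr_out <- classify_and_enrich(mesh, crack_plane(c(100, 0, 0), c(1, 0, 0),
                                                   through = TRUE))
  f1 <- solve_retraction(integration_data(enr_fem, ogden_material()), bcs,
                         duration = 0, increments = 1, allow_no_fixed = TRUE)
  f2 <- solve_retraction(integration_data(enr_out, ogden_material()), bcs,
                         duration = 0, increments = 1, allow_no_fixed = TRUE)
  expect_equal(f1$dofs, f2$dofs, tolerance = 1e-12)
})

test_that("equal-and-opposite rigid face displacements split the cube stress-free", {
  mesh <- cube_mesh()
  crack <- crack_plane(c(17.3, 0, 0), c(1, 0, 0), through = TRUE)
  enr <- classify_and_enrich(mesh, crack)
  id <- integration_data(enr, ogden_material())
  a <- 1.0
  cf <- do.call(rbind, lapply(enr$J, function(nd)
    data.frame(node = nd, face = c(1, -1), ux = c(a, -a), uy = 0, uz = 0)))
  f <- solve_retraction(id, bc_set(crack_face_bcs = cf), duration = 0,
                        increments = 1, allow_no_fixed = TRUE)
  # both half-domains translate rigidly: strain energy -> 0
  expect_lt(f$energy, 1e-6)
  u_right <- displacement_at(enr, f$dofs, c(35, 20, 20))
  u_left <- displacement_at(enr, f$dofs, c(5, 20, 20))
  expect_equal(as.numeric(u_right), c(a, 0, 0), tolerance = 1e-6)
  expect_equal(as.numeric(u_left), c(-a, 0, 0), tolerance = 1e-6)
  # displacement jump across the crack equals 2a at mirrored point pairs
  for (yz in list(c(8, 12), c(20, 20), c(31, 27))) {
    up <- displacement_at(enr, f$dofs, c(17.3 + 1e-3, yz[1], yz[2]))
    um <- displacement_at(enr, f$dofs, c(17.3 - 1e-3, yz[1], yz[2]))
    expect_equal(up[1] - um[1], 2 * a, tolerance = 1e-6)
  }
})

test_that("displacement evaluation reduces to FEM interpolation and nodal values", {
  mesh <- cube_mesh()
  crack <- crack_plane(c(17.3, 0, 0), c(1, 0, 0), through = TRUE)
  enr <- classify_and_enrich(mesh, crack)
  set.seed(9)
  d <- numeric(n_dofs(enr))
  n <- nrow(mesh$nodes)
  d[seq_len(3 * n)] <- rnorm(3 * n, 0, 0.3)
  # enriched DOFs zero: classical interpolation, exact at nodes
  u_node <- displacement_at(enr, d, mesh$nodes[c(1, 100, 500), , drop = FALSE])
  expect_equal(u_node, matrix(d[seq_len(3 * n)], ncol = 3,
                              byrow = TRUE)[c(1, 100, 500), ],
               tolerance = 1e-12)
  # exact at nodes even with nonzero enrichment (shifted basis)
  d[(3 * n + 1):length(d)] <- rnorm(length(d) - 3 * n, 0, 0.3)
  u_node2 <- displacement_at(enr, d, mesh$nodes[enr$J[1:5], , drop = FALSE])
  expect_equal(u_node2, matrix(d[seq_len(3 * n)], ncol = 3,
                               byrow = TRUE)[enr$J[1:5], ],
               tolerance = 1e-12)
  expect_error(displacement_at(enr, d, c(500, 0, 0)), "outside")
})

test_that("energy grows monotonically under a monotone ramp (instantaneous material)", {
  mk <- vol3d(array(1, c(20, 20, 20)), spacing = c(1, 1, 1),
              origin = c(0.5, 0.5, 0.5))
  mesh <- build_octree_hex_mesh(mk, 5)
  A <- 0.06 * diag(3)
  instant <- ogden_material(prony = data.frame(tau = numeric(), g = numeric()))
  id <- integration_data(classify_and_enrich(mesh, NULL), instant)
  energies <- numeric(0)
  for (ninc in 1:4) {
    f <- solve_retraction(id, affine_bcs(mesh, A * ninc / 4), duration = 0,
                          increments = 1, allow_no_fixed = TRUE)
    energies <- c(energies, f$energy)
  }
  expect_true(all(diff(energies) > 0))
})

test_that("solution is invariant under node reordering", {
  mk <- vol3d(array(1, c(15, 10, 10)), spacing = c(1, 1, 1),
              origin = c(0.5, 0.5, 0.5))
  mesh <- build_octree_hex_mesh(mk, 5)
  crack <- crack_plane(c(6.2, 0, 0), c(1, 0, 0), through = TRUE)
  solve_on <- function(mesh) {
    enr <- classify_and_enrich(mesh, crack)
    cf <- do.call(rbind, lapply(enr$J, function(nd)
      data.frame(node = nd, face = c(1, -1), ux = c(0.5, -0.3),
                 uy = 0.1, uz = 0)))
    fixed <- setdiff(which(mesh$nodes[, 1] > 12), enr$J)
    f <- solve_retraction(integration_data(enr, ogden_material()),
                          bc_set(fixed_nodes = fixed, crack_face_bcs = cf),
                          duration = 0, increments = 2)
    list(enr = enr, f = f)
  }
  base <- solve_on(mesh)
  set.seed(4)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes[perm, ]
  mesh2$elems <- matrix(inv[mesh$elems], ncol = 8)
  reord <- solve_on(mesh2)
  probe <- rbind(c(3, 5, 5), c(9, 4, 6), c(13, 8, 3))
  u1 <- displacement_at(base$enr, base$f$dofs, probe)
  u2 <- displacement_at(reord$enr, reord$f$dofs, probe)
  expect_equal(u1, u2, tolerance = 1e-8)
})

test_that("BC handling rejects inconsistent sets and detects missing anchors", {
  mesh <- cube_mesh()
  crack <- crack_plane(c(17.3, 0, 0), c(1, 0, 0), through = TRUE)
  enr <- classify_and_enrich(mesh, crack)
  expect_error(bc_set(fixed_nodes = 1:5,
                      crack_face_bcs = data.frame(node = 3, face = 1, ux = 1,
                                                  uy = 0, uz = 0)),
               "both fixed and crack-prescribed")
  expect_error(bc_set(crack_face_bcs = data.frame(node = 1, face = 2, ux = 0,
                                                  uy = 0, uz = 0)),
               "face sign")
  id <- integration_data(enr, ogden_material())
  fixed <- setdiff(seq_len(nrow(mesh$nodes)), enr$J)[1:12]
  # all prescribed displacements zero -> zero field
  cf0 <- do.call(rbind, lapply(enr$J[1:8], function(nd)
    data.frame(node = nd, face = c(1, -1), ux = 0, uy = 0, uz = 0)))
  f0 <- solve_retraction(id, bc_set(fixed_nodes = fixed,
                                    crack_face_bcs = cf0),
                         duration = 0, increments = 1)
  expect_equal(max(abs(f0$dofs)), 0)
  # no zero-displacement set at all
  cf <- cf0; cf$ux <- cf$face * 0.5
  expect_error(solve_retraction(id, bc_set(crack_face_bcs = cf),
                                duration = 0, increments = 1),
               "zero-displacement")
  # enriched node with only one face prescribed
  expect_error(solve_retraction(id, bc_set(fixed_nodes = fixed,
    crack_face_bcs = data.frame(node = enr$J[1], face = 1, ux = 1, uy = 0,
                                uz = 0)), duration = 0, increments = 1),
    "both crack faces")
})
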