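test_that("octree meshing of a solid cube gives the uniform-grid counts", {
  mesh <- cube_mesh()
  expect_equal(nrow(mesh$elems), 8^3)
  expect_equal(nrow(mesh$nodes), 9^3)
  expect_equal(unname(mesh$h), c(5, 5, 5))
  # element edge never exceeds the requested maximum
  expect_true(all(mesh$h <= 5 + 1e-12))
})

test_that("octree meshing rejects degenerate inputs", {
  mk <- vol3d(array(0, c(10, 10, 10)))
  expect_error(build_octree_hex_mesh(mk, 5), "empty mask")
  mk2 <- vol3d(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_error(build_octree_hex_mesh(mk2, 1.5), "max_edge")
})

test_that("sphere meshing keeps exactly the cells holding masked voxel centres", {
  # 20 mm diameter sphere, 1 mm voxels
  n <- 24
  ctr <- c(12, 12, 12)
  mk <- vol3d(array(0, c(n, n, n)), spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0.5))
  vox <- voxel_centers(mk)
  mk$data[] <- as.numeric(sqrt(rowSums(sweep(vox, 2, ctr)^2)) <= 10)
  mesh <- build_octree_hex_mesh(mk, 5)
  # brute-force oracle: enumerate grid cells over the mask bounding box and
  # keep those containing at least one masked voxel centre
  inside <- vox[mk$data > 0, , drop = FALSE]
  lo <- apply(inside, 2, min) - 0.5
  hi <- apply(inside, 2, max) + 0.5
  ncell <- ceiling((hi - lo) / 5 - 1e-9)
  h <- (hi - lo) / ncell
  keyfun <- function(p) paste(pmin(floor((p - lo) / h), ncell - 1), collapse = ",")
  expected <- sort(unique(apply(inside, 1, keyfun)))
  got <- sort(apply(mesh$cell_ijk, 1, paste, collapse = ","))
  expect_equal(got, expected)
  # every element centre maps back to itself through the lookup
  cen <- t(apply(mesh$elems, 1, function(e) colMeans(mesh$nodes[e, ])))
  expect_equal(locate_elements(mesh, cen), seq_len(nrow(mesh$elems)))
})

test_that("mesh refinement never loses mask coverage", {
  n <- 24
  mk <- vol3d(array(0, c(n, n, n)), spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0.5))
  vox <- voxel_centers(mk)
  mk$data[] <- as.numeric(sqrt(rowSums(sweep(vox, 2, c(12, 12, 12))^2)) <= 10)
  inside <- vox[mk$data > 0, , drop = FALSE]
  for (edge in c(5, 2.5)) {
    mesh <- build_octree_hex_mesh(mk, edge)
    expect_false(anyNA(locate_elements(mesh, inside)))
  }
})

test_that("the level-set pair encodes signed distance and crack side", {
  crack <- crack_plane(c(0, 0, 10), c(0, 0, 1), through = TRUE)
  ls <- level_set_pair(crack, rbind(c(0, 0, 10), c(0, 0, 13), c(5, -2, 7)))
  expect_equal(ls$phi, c(0, 3, -3))
  expect_true(all(ls$psi == -Inf))
  # mirrored points: equal magnitude, opposite sign
  p <- c(1, 2, 14.5); q <- c(1, 2, 5.5)
  lsm <- level_set_pair(crack, rbind(p, q))
  expect_equal(lsm$phi[1], -lsm$phi[2])
  # partial crack: psi measures distance past the front
  crack2 <- crack_plane(c(0, 0, 10), c(0, 0, 1),
                        front_point = c(2, 0, 10), front_dir = c(1, 0, 0))
  ls2 <- level_set_pair(crack2, rbind(c(0, 0, 10), c(5, 0, 10)))
  expect_equal(ls2$psi, c(-2, 3))
})

test_that("heaviside is the sign of phi and jumps by 2 across the crack", {
  expect_equal(heaviside(2), 1)
  expect_equal(heaviside(-0.1), -1)
  expect_equal(heaviside(0.5) - heaviside(-0.5), 2)
})

test_that("tip branch functions have the asymptotic structure", {
  expect_equal(unname(tip_branch_functions(0, 0.3)), matrix(0, 1, 4),
               tolerance = 1e-12)
  expect_equal(unname(tip_branch_functions(1, pi)[1, 1]), 1)
  # only F1 is discontinuous across theta = +/- pi, with jump 2 sqrt(r)
  for (r in c(0.5, 2, 4)) {
    jump <- tip_branch_functions(r, pi) - tip_branch_functions(r, -pi)
    expect_equal(unname(jump[1, 1]), 2 * sqrt(r))
    expect_equal(unname(jump[1, 2:4]), rep(0, 3), tolerance = 1e-12)
  }
  expect_error(tip_branch_functions(-1, 0), "non-negative")
})

test_that("element classification matches brute-force level-set sign tests", {
  mesh <- cube_mesh()
  # crack entirely outside the bounding box: nothing enriched
  enr0 <- classify_and_enrich(mesh, crack_plane(c(100, 0, 0), c(1, 0, 0),
                                                through = TRUE))
  expect_true(all(enr0$elem_class == "standard"))
  expect_length(enr0$J, 0)
  expect_length(enr0$M, 0)
  # through-going plane: crossed elements cut, none tip
  crack <- crack_plane(c(17.3, 0, 0), c(1, 0, 0), through = TRUE)
  enr <- classify_and_enrich(mesh, crack)
  phn <- matrix(level_set_pair(crack, mesh$nodes)$phi[mesh$elems], ncol = 8)
  crossed <- apply(phn, 1, min) < 0 & apply(phn, 1, max) > 0
  expect_equal(enr$elem_class == "cut", crossed)
  expect_length(enr$M, 0)
  expect_setequal(enr$J, unique(as.vector(mesh$elems[crossed, ])))
  # front stopping mid-domain: elements containing the front become tip
  crack2 <- crack_plane(c(17.3, 0, 0), c(1, 0, 0),
                        front_point = c(17.3, 0, 22.2), front_dir = c(0, 0, 1))
  enr2 <- classify_and_enrich(mesh, crack2)
  psn <- matrix(level_set_pair(crack2, mesh$nodes)$psi[mesh$elems], ncol = 8)
  tip_expect <- crossed & apply(psn, 1, min) < 0 & apply(psn, 1, max) >= 0
  expect_equal(enr2$elem_class == "tip", tip_expect)
  expect_true(length(enr2$M) > 0)
  expect_length(intersect(enr2$J, enr2$M), 0)
})

test_that("enrichment bookkeeping: DOF total is 3|I| + 3|J| + 12|M|", {
  mesh <- cube_mesh()
  crack <- crack_plane(c(17.3, 0, 0), c(1, 0, 0),
                       front_point = c(17.3, 0, 22.2), front_dir = c(0, 0, 1))
  enr <- classify_and_enrich(mesh, crack)
  expect_equal(n_dofs(enr),
               3 * nrow(mesh$nodes) + 3 * length(enr$J) + 12 * length(enr$M))
})

test_that("trilinear shape functions are a partition of unity", {
  set.seed(2)
  xi <- matrix(runif(300, -1, 1), ncol = 3)
  sh <- hex_shape(xi)
  expect_equal(rowSums(sh$N), rep(1, 100), tolerance = 1e-12)
  # gradients sum to zero
  for (a in 1:3)
    expect_equal(rowSums(sh$dN[, , a]), rep(0, 100), tolerance = 1e-12)
})

test_that("a crack lying on a mesh plane is snapped, never degenerate", {
  mesh <- cube_mesh()
  crack <- crack_plane(c(15, 0, 0), c(1, 0, 0), through = TRUE)  # on nodes
  enr <- classify_and_enrich(mesh, crack)
  expect_true(all(abs(enr$phi_node) > 0))
  expect_true(sum(enr$elem_class == "cut") > 0)
})
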