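# Independent R-side oracles used across the suite (kept deliberately
# separate from the package's C++ constitutive path).

# isochoric Ogden second Piola-Kirchhoff stress by spectral decomposition
oracle_S_iso <- function(mu0, alpha, F) {
  C <- t(F) %*% F
  e <- eigen(C, symmetric = TRUE)
  lam2 <- e$values
  J <- sqrt(prod(lam2))
  beta <- (2 * mu0 / alpha) * (J^(-1 / 3) * sqrt(lam2))^alpha
  dev <- beta - mean(beta)
  S <- matrix(0, 3, 3)
  for (i in 1:3)
    S <- S + (dev[i] / lam2[i]) * tcrossprod(e$vectors[, i])
  S
}

oracle_S_vol <- function(bulk, F) {
  C <- t(F) %*% F
  J <- sqrt(det(C))
  bulk * (J - 1) * J * solve(C)
}

# closed-form incompressible uniaxial Ogden Cauchy stress
oracle_uniaxial <- function(mu0, alpha, lam) {
  2 * mu0 / alpha * (lam^alpha - lam^(-alpha / 2))
}

# deformation gradients interpolated linearly between knots
interp_F <- function(F_knots, t_knots, t) {
  i <- findInterval(t, t_knots, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(t_knots) - 1)
  w <- (t - t_knots[i]) / (t_knots[i + 1] - t_knots[i])
  (1 - w) * F_knots[[i]] + w * F_knots[[i + 1]]
}

# brute-force Prony convolution: trapezoid quadrature of
# S(t) = Svol(t) + (1 - sum g) Siso(t) + sum_k g_k int e^{-(t-s)/tau_k} dSiso
oracle_convolution <- function(material, F_knots, t_knots, nsub = 1000) {
  tN <- max(t_knots)
  ts <- seq(0, tN, length.out = nsub + 1)
  Siso <- lapply(ts, function(ti)
    oracle_S_iso(material$mu0, material$alpha, interp_F(F_knots, t_knots, ti)))
  FN <- interp_F(F_knots, t_knots, tN)
  S <- oracle_S_vol(material$bulk, FN) +
    (1 - sum(material$prony$g)) * Siso[[length(Siso)]]
  for (k in seq_len(nrow(material$prony))) {
    tau <- material$prony$tau[k]; g <- material$prony$g[k]
    Q <- matrix(0, 3, 3)
    for (j in seq_len(nsub)) {
      smid <- (ts[j] + ts[j + 1]) / 2
      Q <- Q + exp(-(tN - smid) / tau) * (Siso[[j + 1]] - Siso[[j]])
    }
    S <- S + g * Q
  }
  S
}

# a small solid-cube testbed: 40 mm cube mask, 5 mm mesh (512 elements)
cube_mesh <- function(n = 40, max_edge = 5) {
  mk <- vol3d(array(1, c(n, n, n)), spacing = c(1, 1, 1),
              origin = c(0.5, 0.5, 0.5))
  build_octree_hex_mesh(mk, max_edge)
}

boundary_nodes <- function(mesh, lo = 0, hi = 40) {
  which(apply(mesh$nodes, 1, function(p)
    any(abs(p - lo) < 1e-9 | abs(p - hi) < 1e-9)))
}

affine_bcs <- function(mesh, A, nodes = boundary_nodes(mesh)) {
  ub <- mesh$nodes[nodes, , drop = FALSE] %*% t(A)
  bc_set(crack_face_bcs = data.frame(node = nodes, face = 1,
                                     ux = ub[, 1], uy = ub[, 2],
                                     uz = ub[, 3]))
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
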