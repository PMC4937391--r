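test_that("material constructors enforce the physical invariants", {
  expect_error(ogden_material(mu0 = -1), "positive")
  expect_error(ogden_material(prony = data.frame(tau = -1, g = 0.1)),
               "characteristic times")
  expect_error(ogden_material(prony = data.frame(tau = 1, g = -0.1)),
               "non-negative")
  expect_error(ogden_material(prony = data.frame(tau = c(1, 2),
                                                 g = c(0.6, 0.5))),
               "long-term")
  m <- ogden_material()
  expect_s3_class(m, "ogden_material")
  expect_gt(m$bulk, 0)
})

test_that("relaxation modulus reproduces the Prony endpoints and monotonicity", {
  m <- ogden_material()
  expect_equal(relaxation_modulus(m, 0), 842)
  expect_equal(relaxation_modulus(m, 1e9), 842 * (1 - 0.450 - 0.365))
  expect_equal(relaxation_modulus(m, 1e9), 155.77, tolerance = 1e-10)
  # direct numeric evaluation of the Prony sum at one characteristic time
  mu_half <- 842 * (1 - 0.450 * (1 - exp(-1)) - 0.365 * (1 - exp(-0.01)))
  expect_equal(relaxation_modulus(m, 0.5), mu_half)
  expect_equal(round(mu_half, 1), 599.4)
  tgrid <- 10^seq(-3, 4, length.out = 60)
  mu <- relaxation_modulus(m, tgrid)
  expect_true(all(diff(mu) <= 1e-12))
  expect_error(relaxation_modulus(m, -1), "non-negative")
})

test_that("energy density is zero at rest, objective and matches the Ogden form", {
  m <- ogden_material()
  expect_equal(energy_density(m, c(1, 1, 1)), 0)
  expect_error(energy_density(m, c(1, -1, 1)), "positive")
  lam <- c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2))   # isochoric stretch
  W <- energy_density(m, lam)
  expect_equal(W, 2 * m$mu0 / m$alpha^2 * (sum(lam^m$alpha) - 3))
  # permutation invariance of the stretches
  expect_equal(energy_density(m, c(0.9, 1.1, 1.05)),
               energy_density(m, c(1.05, 0.9, 1.1)))
  # objectivity: W depends on F only through the stretches
  set.seed(11)
  for (i in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    if (det(F) <= 0.3) next
    lam <- sqrt(eigen(t(F) %*% F, symmetric = TRUE)$values)
    R <- random_rotation()
    lam2 <- sqrt(eigen(t(R %*% F) %*% (R %*% F), symmetric = TRUE)$values)
    expect_equal(energy_density(m, lam), energy_density(m, lam2),
                 tolerance = 1e-10)
  }
})

test_that("stress vanishes at rest and is frame-indifferent", {
  m <- ogden_material()
  s <- material_stress(m, diag(3))
  expect_equal(max(abs(s$S)), 0, tolerance = 1e-12)
  expect_equal(s$W, 0, tolerance = 1e-12)
  expect_error(material_stress(m, diag(c(-1, 1, 1))), "inverted")
  set.seed(21)
  for (i in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    if (det(F) <= 0.3) next
    R <- random_rotation()
    c1 <- material_stress(m, F)$cauchy
    c2 <- material_stress(m, R %*% F)$cauchy
    expect_lt(max(abs(R %*% c1 %*% t(R) - c2)), 1e-10 * max(abs(c1)))
  }
})

test_that("instantaneous uniaxial response matches the incompressible closed form", {
  # near-incompressible bulk so the compressible model approaches the
  # incompressible oracle
  m <- ogden_material(poisson = 0.4995)
  uniaxial_sigma <- function(lam) {
    lt <- uniroot(function(t)
      material_stress(m, diag(c(lam, t, t)))$cauchy[2, 2],
      c(0.4, 2.5), tol = 1e-12)$root
    material_stress(m, diag(c(lam, lt, lt)))$cauchy[1, 1]
  }
  for (lam in c(0.7, 0.85, 1.0 + 1e-6, 1.1, 1.3)) {
    s <- uniaxial_sigma(lam)
    o <- oracle_uniaxial(842, -4.7, lam)
    if (abs(o) > 1e-3) expect_lt(abs(s / o - 1), 0.01)
  }
  # spot value: lambda = 1.1 gives ~219 Pa
  expect_equal(uniaxial_sigma(1.1), 219.3, tolerance = 0.01)
})

test_that("held stretch relaxes the isochoric stress to the long-term ratio", {
  m <- ogden_material()
  Fh <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))   # isochoric: no vol part
  s0 <- material_stress(m, Fh, fresh_state(m), dt = 0)
  st <- s0$state
  sN <- s0
  for (i in 1:400) {                                 # 2000 s >> tau2 = 50 s
    sN <- material_stress(m, Fh, st, dt = 5)
    st <- sN$state
  }
  expect_equal(sN$S / s0$S[1], (1 - 0.450 - 0.365) * s0$S / s0$S[1],
               tolerance = 1e-6)
})

test_that("Prony recursion matches brute-force convolution quadrature", {
  m <- ogden_material()
  set.seed(33)
  for (rep in 1:3) {
    nk <- 6
    t_knots <- seq(0, 20, length.out = nk)
    F_knots <- list(diag(3))
    for (i in 2:nk)
      F_knots[[i]] <- F_knots[[i - 1]] + matrix(rnorm(9, 0, 0.04), 3)
    # recursive update along the piecewise-linear history, substepped so the
    # within-step linear-Siso assumption holds well
    st <- fresh_state(m)
    nstep <- 10
    tt <- seq(0, 20, length.out = nk * nstep + 1)
    s <- NULL
    for (j in 2:length(tt)) {
      s <- material_stress(m, interp_F(F_knots, t_knots, tt[j]), st,
                           dt = diff(tt)[1])
      st <- s$state
    }
    S_rec <- s$S_mat
    S_conv <- oracle_convolution(m, F_knots, t_knots, nsub = 1000)
    expect_lt(max(abs(S_rec - S_conv)) / max(abs(S_conv)), 0.005)
  }
})

test_that("analytic tangent agrees with finite differences of the stress", {
  m <- ogden_material()
  set.seed(5)
  for (i in 1:6) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    if (det(F) <= 0.3) next
    for (dt in c(0, 2)) {
      Da <- material_tangent(m, F, fresh_state(m), dt)
      Df <- material_tangent(m, F, fresh_state(m), dt, method = "fd")
      expect_lt(max(abs(Da - Df)) / max(abs(Df)), 1e-4)
      expect_equal(Da, t(Da), tolerance = 1e-9)
    }
  }
  # degenerate (equal-stretch) states use the l'Hopital branch
  for (F in list(diag(3), 1.07 * diag(3), diag(c(1.1, 1.1, 0.92)))) {
    Da <- material_tangent(m, F)
    Df <- material_tangent(m, F, method = "fd")
    expect_lt(max(abs(Da - Df)) / max(abs(Df)), 1e-4)
  }
})

test_that("the linear-elastic plug-in has a constant tangent", {
  m <- linear_material(mu = 842, poisson = 0.45)
  D1 <- material_tangent(m, diag(3))
  set.seed(8)
  D2 <- material_tangent(m, diag(3) + matrix(rnorm(9, 0, 0.05), 3))
  expect_equal(D1, D2)
  expect_equal(D1[4, 4], 842)
  expect_equal(D1[1, 2], m$bulk - 2 * 842 / 3)
})

test_that("material config round-trips the defaults and custom blocks", {
  m <- material_from_config(NULL)
  expect_equal(m$mu0, 842)
  expect_equal(m$alpha, -4.7)
  expect_equal(m$prony$tau, c(0.5, 50))
  m2 <- material_from_config(list(mu0_pa = 1000, alpha = -3,
                                  prony = list(list(tau_s = 1, g = 0.2)),
                                  poisson = 0.45))
  expect_equal(m2$prony$g, 0.2)
  m3 <- material_from_config(list(model = "linear", mu0_pa = 500))
  expect_s3_class(m3, "linear_material")
})
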