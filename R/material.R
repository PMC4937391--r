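#' Ogden hyper-viscoelastic material for brain parenchyma
#'
#' Constructs the constitutive model used for the retraction simulation: a
#' one-term Ogden strain-energy function of the principal stretches with a
#' Prony-series stress-relaxation kernel,
#' \deqn{W = \frac{2\mu_0}{\alpha^2}(\bar\lambda_1^\alpha +
#'   \bar\lambda_2^\alpha + \bar\lambda_3^\alpha - 3), \qquad
#'   \mu(t) = \mu_0\Big(1 - \sum_k g_k\big(1 - e^{-t/\tau_k}\big)\Big).}
#' The energy is split into an isochoric Ogden part (relaxing in time) and a
#' quadratic volumetric penalty \eqn{U = K/2\,(J-1)^2} (purely elastic); the
#' bulk modulus \eqn{K} is derived from an equivalent Poisson ratio, 0.49 by
#' default (near-incompressible tissue).
#'
#' Defaults are the porcine-brain parameters used throughout the package:
#' \eqn{\mu_0 = 842} Pa, \eqn{\alpha = -4.7}, and Prony pairs
#' \eqn{(\tau_1, g_1) = (0.5\,\mathrm{s}, 0.450)},
#' \eqn{(\tau_2, g_2) = (50\,\mathrm{s}, 0.365)}.
#'
#' @param mu0 instantaneous shear modulus, Pa.
#' @param alpha Ogden exponent (any non-zero real).
#' @param prony data.frame with columns `tau` (s) and `g` (dimensionless),
#'   one row per Prony term; may have zero rows for a purely hyperelastic
#'   material.
#' @param poisson equivalent Poisson ratio used to derive the bulk modulus.
#' @return an object of class `ogden_material`.
#' @seealso [linear_material()] for the linear-elastic comparison model,
#'   [relaxation_modulus()], [energy_density()], [material_stress()].
#' @export
ogden_material <- function(mu0 = 842, alpha = -4.7,
                           prony = data.frame(tau = c(0.5, 50),
                                              g = c(0.450, 0.365)),
                           poisson = 0.49) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.numeric(alpha),
            length(alpha) == 1L, is.data.frame(prony))
  if (mu0 <= 0) stop("mu0 must be positive")
  if (alpha == 0) stop("alpha must be non-zero")
  if (nrow(prony) > 0) {
    if (!all(c("tau", "g") %in% names(prony)))
      stop("prony needs columns 'tau' and 'g'")
    if (any(prony$tau <= 0)) stop("all Prony characteristic times must be positive")
    if (any(prony$g < 0)) stop("Prony relaxation coefficients must be non-negative")
    if (sum(prony$g) >= 1)
      stop("sum of relaxation coefficients must be < 1 (long-term modulus must stay positive)")
  }
  if (poisson <= 0 || poisson >= 0.5) stop("poisson must lie in (0, 0.5)")
  bulk <- 2 * mu0 * (1 + poisson) / (3 * (1 - 2 * poisson))
  structure(list(type = "ogden", mu0 = mu0, alpha = alpha,
                 prony = prony, poisson = poisson, bulk = bulk),
            class = c("ogden_material", "retract_material"))
}

#' Linear-elastic (St Venant-Kirchhoff) comparison material
#'
#' Plug-in material implementing the same interface as [ogden_material()],
#' used for the linear-elastic XFEM comparison mode. The shear modulus and
#' bulk modulus play the roles of the Lame constants
#' \eqn{\mu} and \eqn{\lambda = K - 2\mu/3}.
#'
#' @inheritParams ogden_material
#' @param mu shear modulus, Pa.
#' @return an object of class `linear_material`.
#' @export
linear_material <- function(mu = 842, poisson = 0.49) {
  if (mu <= 0) stop("mu must be positive")
  if (poisson <= 0 || poisson >= 0.5) stop("poisson must lie in (0, 0.5)")
  bulk <- 2 * mu * (1 + poisson) / (3 * (1 - 2 * poisson))
  structure(list(type = "linear", mu0 = mu, alpha = NA_real_,
                 prony = data.frame(tau = numeric(), g = numeric()),
                 poisson = poisson, bulk = bulk),
            class = c("linear_material", "retract_material"))
}

#' @export
print.retract_material <- function(x, ...) {
  cat(sprintf("<%s material>  mu0 = %g Pa", x$type, x$mu0))
  if (x$type == "ogden") cat(sprintf(", alpha = %g", x$alpha))
  cat(sprintf(", poisson = %g (K = %.4g Pa)\n", x$poisson, x$bulk))
  if (nrow(x$prony) > 0) {
    for (k in seq_len(nrow(x$prony)))
      cat(sprintf("  Prony %d: tau = %g s, g = %g\n", k,
                  x$prony$tau[k], x$prony$g[k]))
  }
  invisible(x)
}

mat_type_code <- function(material) {
  if (material$type == "linear") 1L else 0L
}

mat_g <- function(material) as.numeric(material$prony$g)
mat_tau <- function(material) as.numeric(material$prony$tau)

#' Number of internal-history scalars per quadrature point
#' @noRd
state_size <- function(material) {
  if (material$type == "linear") return(1L)  # unused placeholder
  6L * (nrow(material$prony) + 1L)
}

#' Fresh (zero-history) viscoelastic state
#'
#' Internal stress-like history variables, one symmetric tensor (Voigt 6)
#' per Prony term plus the previous isochoric stress, all zero in the
#' undeformed reference state.
#'
#' @param material a material object.
#' @param n_gp number of quadrature points.
#' @return matrix `state_size x n_gp` of zeros with attribute `time = 0`.
#' @export
fresh_state <- function(material, n_gp = 1L) {
  s <- matrix(0, nrow = state_size(material), ncol = n_gp)
  attr(s, "time") <- 0
  s
}

#' Shear relaxation modulus
#'
#' Evaluates \eqn{\mu(t) = \mu_0 (1 - \sum_k g_k (1 - e^{-t/\tau_k}))}:
#' \eqn{\mu(0) = \mu_0} and the long-term modulus is
#' \eqn{\mu_0 (1 - \sum_k g_k)}.
#'
#' @param material an [ogden_material()].
#' @param t time, s (vectorised, all `>= 0`).
#' @return shear modulus, Pa.
#' @export
relaxation_modulus <- function(material, t) {
  if (any(t < 0)) stop("time must be non-negative")
  g <- mat_g(material); tau <- mat_tau(material)
  if (length(g) == 0) return(rep(material$mu0, length(t)))
  rel <- vapply(t, function(ti) sum(g * (1 - exp(-ti / tau))), numeric(1))
  material$mu0 * (1 - rel)
}

#' Instantaneous strain-energy density
#'
#' Ogden isochoric energy plus the volumetric penalty, evaluated from the
#' principal stretches. Zero at the undeformed state and invariant under
#' permutation of the stretches.
#'
#' @param material a material object.
#' @param stretches numeric length-3 vector of principal stretches, all `> 0`.
#' @return energy per reference volume, Pa.
#' @export
energy_density <- function(material, stretches) {
  stopifnot(length(stretches) == 3L)
  if (any(stretches <= 0)) stop("principal stretches must be positive")
  J <- prod(stretches)
  if (material$type == "linear") {
    # Green-Lagrange strain of a pure stretch
    E <- (stretches^2 - 1) / 2
    mu <- material$mu0; lam <- material$bulk - 2 * mu / 3
    return(0.5 * lam * sum(E)^2 + mu * sum(E^2))
  }
  lbar <- stretches * J^(-1 / 3)
  2 * material$mu0 / material$alpha^2 * (sum(lbar^material$alpha) - 3) +
    material$bulk / 2 * (J - 1)^2
}

#' Viscoelastic stress update at a material point
#'
#' Second Piola-Kirchhoff stress (and its push-forward Cauchy stress) for a
#' deformation gradient held over a time increment `dt`, with the recursive
#' Prony internal-variable update (exact for stress histories varying
#' linearly within the step). `dt = 0` gives the instantaneous response.
#'
#' @param material a material object.
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param state per-point state vector/one-column matrix from [fresh_state()].
#' @param dt time increment, s, `>= 0`.
#' @return list with `S` (second Piola-Kirchhoff, Voigt 6), `S_mat` (3x3),
#'   `cauchy` (3x3), `state` (updated history), `W` (instantaneous energy
#'   density, Pa).
#' @export
material_stress <- function(material, F, state = fresh_state(material), dt = 0) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  if (dt < 0) stop("dt must be non-negative")
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  cpp_point_constitutive(F, mat_type_code(material), material$mu0,
                         ifelse(is.na(material$alpha), 0, material$alpha),
                         material$bulk, mat_g(material), mat_tau(material),
                         as.numeric(state), dt, FALSE, FALSE)
}

#' Consistent material tangent at a point
#'
#' Fourth-order tangent \eqn{dS/dE} in Voigt form (6x6, engineering shear
#' strains), consistent with [material_stress()] for the same `(state, dt)`.
#'
#' @inheritParams material_stress
#' @param method `"analytic"` (spectral closed form, the solver path) or
#'   `"fd"` (central differences of [material_stress()], the independent
#'   cross-check).
#' @return 6x6 symmetric tangent matrix, Pa.
#' @export
material_tangent <- function(material, F, state = fresh_state(material), dt = 0,
                             method = c("analytic", "fd")) {
  method <- match.arg(method)
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  if (dt < 0) stop("dt must be non-negative")
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  out <- cpp_point_constitutive(F, mat_type_code(material), material$mu0,
                                ifelse(is.na(material$alpha), 0, material$alpha),
                                material$bulk, mat_g(material), mat_tau(material),
                                as.numeric(state), dt, TRUE,
                                identical(method, "fd"))
  out$D
}

#' Read a material from a config block
#'
#' Accepts the `material:` block of a run configuration, with keys
#' `model` ("ogden" or "linear"), `mu0_pa`, `alpha`,
#' `prony` (list of `{tau_s, g}`) and `poisson`. Missing keys fall back to
#' the porcine-brain defaults.
#'
#' @param block named list (parsed YAML/JSON), or `NULL` for all defaults.
#' @return a material object.
#' @export
material_from_config <- function(block = NULL) {
  if (is.null(block)) return(ogden_material())
  model <- block$model %||% "ogden"
  poisson <- block$poisson %||% 0.49
  if (identical(model, "linear"))
    return(linear_material(mu = block$mu0_pa %||% 842, poisson = poisson))
  prony <- if (is.null(block$prony)) {
    data.frame(tau = c(0.5, 50), g = c(0.450, 0.365))
  } else {
    data.frame(tau = vapply(block$prony, function(p) p$tau_s, numeric(1)),
               g = vapply(block$prony, function(p) p$g, numeric(1)))
  }
  ogden_material(mu0 = block$mu0_pa %||% 842, alpha = block$alpha %||% -4.7,
                 prony = prony, poisson = poisson)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
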