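#' Planar crack geometry with a two-level-set representation
#'
#' The crack (the tissue discontinuity opened by the retractor) is the set
#' `{phi = 0, psi <= 0}`, where `phi` is the signed normal distance to the
#' crack plane and `psi` the signed distance ahead of the crack front.
#' A through-going crack (`through = TRUE`) has `psi = -Inf` everywhere,
#' in which case no crack-tip enrichment is needed.
#'
#' @param point a point on the crack plane, mm.
#' @param normal plane normal (normalised internally).
#' @param front_point,front_dir define the crack front for a partial crack:
#'   `psi(x) = (x - front_point) . front_dir` with `front_dir` pointing from
#'   the cracked region towards intact tissue (in-plane, normalised
#'   internally). Ignored when `through = TRUE`.
#' @param through logical; `TRUE` for a crack cutting fully through the
#'   domain.
#' @return object of class `crack_geometry`.
#' @export
crack_plane <- function(point, normal, front_point = NULL, front_dir = NULL,
                        through = is.null(front_point)) {
  normal <- normal / sqrt(sum(normal^2))
  if (!through) {
    if (is.null(front_point) || is.null(front_dir))
      stop("partial crack needs front_point and front_dir")
    # project the front direction into the crack plane
    front_dir <- front_dir - sum(front_dir * normal) * normal
    nrm <- sqrt(sum(front_dir^2))
    if (nrm < 1e-12) stop("front_dir must not be parallel to the crack normal")
    front_dir <- front_dir / nrm
  }
  structure(list(point = as.numeric(point), normal = as.numeric(normal),
                 front_point = if (through) NULL else as.numeric(front_point),
                 front_dir = if (through) NULL else as.numeric(front_dir),
                 through = through),
            class = "crack_geometry")
}

#' @export
print.crack_geometry <- function(x, ...) {
  cat(sprintf("<crack_geometry> plane through (%s), normal (%s), %s\n",
              paste(signif(x$point, 4), collapse = ", "),
              paste(signif(x$normal, 4), collapse = ", "),
              if (x$through) "through-going" else "with crack front"))
  invisible(x)
}

#' Evaluate the crack level-set pair
#'
#' @param crack a [crack_plane()].
#' @param pts `n x 3` world coordinates, mm.
#' @return list with vectors `phi` (signed normal distance, mm) and `psi`
#'   (signed distance past the crack front, mm; `-Inf` for a through crack),
#'   plus the constant gradients `gphi`, `gpsi`.
#' @export
level_set_pair <- function(crack, pts) {
  pts <- matrix(pts, ncol = 3L)
  phi <- as.numeric(sweep(pts, 2, crack$point, "-") %*% crack$normal)
  if (crack$through) {
    psi <- rep(-Inf, nrow(pts))
    gpsi <- c(0, 0, 0)
  } else {
    psi <- as.numeric(sweep(pts, 2, crack$front_point, "-") %*% crack$front_dir)
    gpsi <- crack$front_dir
  }
  list(phi = phi, psi = psi, gphi = crack$normal, gpsi = gpsi)
}

#' Heaviside enrichment function
#'
#' Sign of the crack level set `phi`, i.e. +1 on the positive side of the
#' crack plane and -1 on the negative side. The nodal level-set snap rule
#' guarantees `phi != 0` at evaluation points of the discretisation; an
#' exact 0 is mapped to +1 for definiteness.
#'
#' @param phi signed distance(s) to the crack plane.
#' @return +1 / -1.
#' @export
heaviside <- function(phi) ifelse(phi >= 0, 1, -1)

#' Crack-tip branch functions
#'
#' The standard asymptotic enrichment set
#' \deqn{F_1 = \sqrt{r}\sin(\theta/2),\; F_2 = \sqrt{r}\cos(\theta/2),\;
#'       F_3 = \sqrt{r}\sin(\theta/2)\sin\theta,\;
#'       F_4 = \sqrt{r}\cos(\theta/2)\sin\theta,}
#' in crack-tip polar coordinates; only `F1` is discontinuous across the
#' crack faces (`theta = +/- pi`).
#'
#' @param r radial distance from the crack front, mm (`>= 0`).
#' @param theta angle in `(-pi, pi]`, measured from the intact-side plane
#'   direction, positive towards `phi > 0`.
#' @return `n x 4` matrix of branch-function values.
#' @export
tip_branch_functions <- function(r, theta) {
  if (any(r < 0)) stop("r must be non-negative")
  sr <- sqrt(r)
  cbind(F1 = sr * sin(theta / 2),
        F2 = sr * cos(theta / 2),
        F3 = sr * sin(theta / 2) * sin(theta),
        F4 = sr * cos(theta / 2) * sin(theta))
}

# branch functions and their spatial gradients from the level-set pair
tip_branch_eval <- function(crack, pts) {
  pts <- matrix(pts, ncol = 3L)
  ls <- level_set_pair(crack, pts)
  r <- sqrt(ls$phi^2 + ls$psi^2)
  theta <- atan2(ls$phi, ls$psi)
  Fv <- tip_branch_functions(r, theta)
  # dF/dr, dF/dtheta
  sr <- sqrt(pmax(r, 1e-300))
  s2 <- sin(theta / 2); c2 <- cos(theta / 2); st <- sin(theta); ct <- cos(theta)
  dFdr <- cbind(s2, c2, s2 * st, c2 * st) / (2 * sr)
  dFdt <- sr * cbind(c2 / 2, -s2 / 2, c2 * st / 2 + s2 * ct,
                     -s2 * st / 2 + c2 * ct)
  # grad r, grad theta from constant grad phi / grad psi
  gr <- (outer(ls$phi, ls$gphi) + outer(ls$psi, ls$gpsi)) / pmax(r, 1e-300)
  gt <- (outer(ls$psi, ls$gphi) - outer(ls$phi, ls$gpsi)) / pmax(r^2, 1e-300)
  grad <- array(0, c(nrow(pts), 4, 3))
  for (l in 1:4) for (a in 1:3)
    grad[, l, a] <- dFdr[, l] * gr[, a] + dFdt[, l] * gt[, a]
  list(F = Fv, grad = grad, r = r, theta = theta)
}
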