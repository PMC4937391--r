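# Quadrature and integration-data precomputation.
#
# Standard (uncut, unblended) hexahedra use a 2x2x2 Gauss rule. Elements cut
# by the crack, containing the crack front, or blending tip enrichment use a
# regular n x n x n sub-cell midpoint rule so that each sample point lies
# strictly on one side of the discontinuity; the Heaviside factor is then
# constant per sample and the enriched integrand is smooth there.

gauss2 <- 1 / sqrt(3)
gauss_pts8 <- as.matrix(expand.grid(x = c(-gauss2, gauss2),
                                    y = c(-gauss2, gauss2),
                                    z = c(-gauss2, gauss2)))

subcell_pts <- function(nsub) {
  s <- (seq_len(nsub) - 0.5) / nsub * 2 - 1
  as.matrix(expand.grid(x = s, y = s, z = s))
}

# gradients (physical, world mm) of the generalised basis at local points xi
# of element e; returns 3 x (npts * nb) matrix (basis fastest) plus values.
basis_at_local <- function(enr, e, xi, basis = element_basis(enr, e)) {
  mesh <- enr$mesh
  xi <- matrix(xi, ncol = 3L)
  npt <- nrow(xi)
  sh <- hex_shape(xi)
  gradN <- sh$dN
  for (a in 1:3) gradN[, , a] <- gradN[, , a] * (2 / mesh$h[a])
  # world points
  n0 <- mesh$nodes[mesh$elems[e, 1], ]
  pts <- sweep((xi + 1) / 2, 2, mesh$h, "*")
  pts <- sweep(pts, 2, n0, "+")
  nb <- length(basis$node)
  vals <- matrix(0, npt, nb)
  grads <- array(0, c(npt, nb, 3))
  need_H <- any(basis$type == 1L)
  need_tip <- any(basis$type == 2L)
  s <- NULL
  if (need_H) {
    ls <- level_set_pair(enr$crack, pts)
    s <- heaviside(ls$phi)
  }
  tb <- if (need_tip) tip_branch_eval(enr$crack, pts) else NULL
  loc_a <- match(basis$node, mesh$elems[e, ])  # local node index 1..8
  for (c in seq_len(nb)) {
    a <- loc_a[c]
    if (basis$type[c] == 0L) {
      vals[, c] <- sh$N[, a]
      grads[, c, ] <- gradN[, a, ]
    } else if (basis$type[c] == 1L) {
      fac <- s - enr$H_node[basis$node[c]]
      vals[, c] <- sh$N[, a] * fac
      for (d in 1:3) grads[, c, d] <- gradN[, a, d] * fac
    } else {
      l <- basis$branch[c]
      Fl0 <- enr$tipF_node[enr$m_index[basis$node[c]], l]
      fac <- tb$F[, l] - Fl0
      vals[, c] <- sh$N[, a] * fac
      for (d in 1:3)
        grads[, c, d] <- gradN[, a, d] * fac + sh$N[, a] * tb$grad[, l, d]
    }
  }
  list(vals = vals, grads = grads, pts = pts)
}

#' Precompute XFEM integration data
#'
#' Builds the flattened quadrature tables (basis gradients, weights, DOF
#' columns, fresh material state) consumed by the assembly kernel.
#'
#' @param enr an `enriched_hex_mesh`.
#' @param material a material object.
#' @param nsub sub-cell subdivisions per axis for enriched elements.
#' @return object of class `xfem_idata`.
#' @export
integration_data <- function(enr, material, nsub = 4L) {
  mesh <- enr$mesh
  ne <- nrow(mesh$elems)
  vol_gp_gauss <- prod(mesh$h) / 8      # weight per 2x2x2 Gauss point
  vol_gp_sub <- prod(mesh$h) / nsub^3   # weight per sub-cell midpoint
  has_M <- vapply(seq_len(ne), function(e)
    any(enr$m_index[mesh$elems[e, ]] > 0), logical(1))
  enriched_quad <- enr$elem_class != "standard" | has_M
  elem_nb <- integer(ne); elem_ngp <- integer(ne)
  basis_dofs_l <- vector("list", ne)
  grads_l <- vector("list", ne)
  w_l <- vector("list", ne)
  # shared gradient block for plain standard elements (identical geometry)
  std_basis_template <- NULL
  for (e in seq_len(ne)) {
    basis <- element_basis(enr, e)
    nb <- length(basis$node)
    elem_nb[e] <- nb
    basis_dofs_l[[e]] <- rbind(basis$dof0, basis$dof0 + 1L, basis$dof0 + 2L)
    if (!enriched_quad[e]) {
      if (is.null(std_basis_template)) {
        bb <- basis_at_local(enr, e, gauss_pts8, basis)
        g <- matrix(0, 3, 8 * nb)
        for (q in 1:8) g[, (q - 1) * nb + seq_len(nb)] <- t(bb$grads[q, , ])
        std_basis_template <- g
      }
      elem_ngp[e] <- 8L
      grads_l[[e]] <- std_basis_template
      w_l[[e]] <- rep(vol_gp_gauss, 8)
    } else {
      xi <- subcell_pts(nsub)
      bb <- basis_at_local(enr, e, xi, basis)
      npt <- nrow(xi)
      g <- matrix(0, 3, npt * nb)
      for (q in seq_len(npt)) g[, (q - 1) * nb + seq_len(nb)] <- t(bb$grads[q, , ])
      elem_ngp[e] <- npt
      grads_l[[e]] <- g
      w_l[[e]] <- rep(vol_gp_sub, npt)
    }
  }
  gp_w <- unlist(w_l)
  structure(list(enr = enr, material = material,
                 elem_nb = elem_nb, elem_ngp = elem_ngp,
                 basis_dofs = do.call(cbind, basis_dofs_l),
                 gp_grad = do.call(cbind, grads_l),
                 gp_w = gp_w, n_gp = length(gp_w), ndof = enr$ndof,
                 nsub = nsub, cache = new.env(parent = emptyenv())),
            class = "xfem_idata")
}

#' Assemble the XFEM residual and tangent
#'
#' Internal-force residual (no external tractions: the retraction problem is
#' displacement-driven with traction-free remaining boundary) and, when
#' requested, the sparse consistent tangent, for the current DOF vector and
#' material state over one time increment `dt`.
#'
#' @param idata an [integration_data()] object.
#' @param dofs numeric DOF vector (length `n_dofs(enr)`).
#' @param state material state matrix (`state_size x n_gp`), e.g. from
#'   [fresh_state()].
#' @param dt time increment, s.
#' @param tangent logical; also assemble the sparse tangent matrix.
#' @return list with `resid`, `state` (updated, uncommitted), `energy`
#'   (total instantaneous strain energy, J/mm^3 scale: Pa x mm^3), and `K`
#'   (a `dgCMatrix`) when `tangent = TRUE`.
#' @export
assemble_system <- function(idata, dofs, state = NULL, dt = 0, tangent = TRUE) {
  stopifnot(inherits(idata, "xfem_idata"))
  if (length(dofs) != idata$ndof) stop("DOF vector has wrong length")
  if (is.null(state)) state <- fresh_state(idata$material, idata$n_gp)
  m <- idata$material
  cache <- idata$cache
  have_pattern <- !is.null(cache$Ktemplate)
  out <- cpp_assemble(dofs, idata$ndof, idata$elem_nb, idata$elem_ngp,
                      idata$basis_dofs, idata$gp_grad, idata$gp_w,
                      mat_type_code(m), m$mu0,
                      ifelse(is.na(m$alpha), 0, m$alpha), m$bulk,
                      mat_g(m), mat_tau(m), state, dt, tangent,
                      !have_pattern)
  res <- list(resid = out$resid, state = out$state, energy = out$energy)
  if (tangent) {
    if (!have_pattern) {
      # first tangent assembly: build the sparse pattern once and remember
      # where every element-matrix entry lands in the compressed columns
      K <- Matrix::sparseMatrix(i = out$Ki + 1L, j = out$Kj + 1L,
                                x = out$Kx, dims = c(idata$ndof, idata$ndof))
      nnzcol <- diff(K@p)
      ukey <- rep.int(seq_len(idata$ndof), nnzcol) - 1
      ukey <- ukey * idata$ndof + K@i          # sorted: column-major keys
      key <- as.numeric(out$Kj) * idata$ndof + as.numeric(out$Ki)
      cache$map <- findInterval(key, ukey)
      cache$nnz <- length(K@x)
      cache$Ktemplate <- K
      res$K <- K
    } else {
      K <- cache$Ktemplate
      K@x <- cpp_accumulate(cache$map, out$Kx, cache$nnz)
      res$K <- K
    }
  }
  res
}

#' Evaluate the XFEM displacement field at arbitrary points
#'
#' Shifted-basis field
#' `u(x) = sum_I N_i u_i + sum_J N_j (H(x) - H_j) a_j +
#'  sum_M N_m sum_l (F_l(x) - F_l(x_m)) b_m^l`;
#' enriched terms vanish at the nodes, so nodal values equal the standard
#' DOFs. Each point is evaluated on its own side of the crack (the sign of
#' its `phi` selects the Heaviside branch).
#'
#' @param enr an `enriched_hex_mesh`.
#' @param dofs DOF vector.
#' @param pts `n x 3` world coordinates, mm.
#' @param outside how to treat points outside the mesh: `"error"` or
#'   `"zero"`.
#' @return `n x 3` matrix of displacements, mm.
#' @export
displacement_at <- function(enr, dofs, pts, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  pts <- matrix(pts, ncol = 3L)
  eid <- locate_elements(enr$mesh, pts)
  if (anyNA(eid) && outside == "error")
    stop(sprintf("%d point(s) outside the meshed domain", sum(is.na(eid))))
  u <- matrix(0, nrow(pts), 3)
  ok <- which(!is.na(eid))
  if (length(ok) == 0) return(u)
  for (e in unique(eid[ok])) {
    sel <- ok[eid[ok] == e]
    xi <- hex_local_coords(enr$mesh, rep(e, length(sel)),
                           pts[sel, , drop = FALSE])
    basis <- element_basis(enr, e)
    bb <- basis_at_local(enr, e, xi, basis)
    for (c in seq_along(basis$node)) {
      dv <- dofs[basis$dof0[c] + 1:3]
      u[sel, ] <- u[sel, ] + outer(bb$vals[, c], dv)
    }
  }
  u
}
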