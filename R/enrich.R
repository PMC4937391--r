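#' Classify elements against the crack and build the enriched DOF map
#'
#' Elements whose nodal `phi` values change sign are *cut* when the crack
#' surface extends across them (all nodal `psi < 0`) and *tip* elements when
#' the crack front passes through them (`psi` changes sign); all others are
#' standard. Nodes of cut elements form the Heaviside-enriched set `J`
#' (3 extra DOFs `a_j` each); nodes of tip elements form the tip-enriched
#' set `M` (12 extra DOFs `b_m^l`, `l = 1..4`); `J` and `M` are disjoint
#' subsets of the full node set `I`, so the total DOF count is
#' `3|I| + 3|J| + 12|M|`.
#'
#' Nodal level sets are snapped away from zero (`|phi| < snap * edge` is
#' shifted to `+snap * edge`) so a crack coincident with a mesh face never
#' produces a degenerate cut.
#'
#' @param mesh a `hex_mesh`.
#' @param crack a [crack_plane()], or `NULL` for no crack (plain FEM).
#' @param snap relative nodal snap tolerance (fraction of the element edge).
#' @return object of class `enriched_hex_mesh`.
#' @export
classify_and_enrich <- function(mesh, crack, snap = 1e-6) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  if (is.null(crack)) {
    phi <- rep(1, n); psi <- rep(Inf, n)
    eclass <- rep("standard", ne)
  } else {
    ls <- level_set_pair(crack, mesh$nodes)
    tol <- snap * min(mesh$h)
    phi <- ls$phi
    phi[abs(phi) < tol] <- tol          # deterministic positive-side snap
    psi <- ls$psi
    phn <- matrix(phi[mesh$elems], ncol = 8)
    psn <- matrix(psi[mesh$elems], ncol = 8)
    crossed <- apply(phn, 1, min) < 0 & apply(phn, 1, max) > 0
    psmin <- apply(psn, 1, min); psmax <- apply(psn, 1, max)
    eclass <- rep("standard", ne)
    eclass[crossed & psmax < 0] <- "cut"
    eclass[crossed & psmin < 0 & psmax >= 0] <- "tip"
  }
  M <- sort(unique(as.vector(mesh$elems[eclass == "tip", ])))
  J <- setdiff(sort(unique(as.vector(mesh$elems[eclass == "cut", ]))), M)
  H_node <- heaviside(phi)
  # shifted tip enrichment needs the nodal branch-function values
  tipF_node <- NULL
  if (length(M) > 0)
    tipF_node <- tip_branch_eval(crack, mesh$nodes[M, , drop = FALSE])$F
  # DOF map: standard 3/node, then a_j 3/J-node, then b_m 12/M-node
  a_dof0 <- 3L * n
  b_dof0 <- a_dof0 + 3L * length(J)
  ndof <- b_dof0 + 12L * length(M)
  a_index <- integer(n); a_index[J] <- seq_along(J)   # rank within J
  m_index <- integer(n); m_index[M] <- seq_along(M)
  structure(list(mesh = mesh, crack = crack, elem_class = eclass,
                 phi_node = phi, psi_node = psi, H_node = H_node,
                 J = J, M = M, a_index = a_index, m_index = m_index,
                 tipF_node = tipF_node,
                 a_dof0 = a_dof0, b_dof0 = b_dof0, ndof = ndof),
            class = "enriched_hex_mesh")
}

#' @export
print.enriched_hex_mesh <- function(x, ...) {
  print(x$mesh)
  cat(sprintf("  crack: %s | elements: %d standard, %d cut, %d tip\n",
              if (is.null(x$crack)) "none" else "planar",
              sum(x$elem_class == "standard"), sum(x$elem_class == "cut"),
              sum(x$elem_class == "tip")))
  cat(sprintf("  enriched nodes: |J| = %d (Heaviside), |M| = %d (tip); %d DOFs\n",
              length(x$J), length(x$M), x$ndof))
  invisible(x)
}

#' Total number of degrees of freedom
#' @param enr an `enriched_hex_mesh`.
#' @return integer DOF count `3|I| + 3|J| + 12|M|`.
#' @export
n_dofs <- function(enr) enr$ndof

# Per-element generalised basis table. Each basis function carries 3 DOFs;
# types: 0 standard (node a), 1 Heaviside (node a), 2 tip (node a, branch l).
# Returns list(node, type, branch, dof0) where dof0 is the 0-based global id
# of the x-DOF of that basis function.
element_basis <- function(enr, e) {
  nodes <- enr$mesh$elems[e, ]
  node <- nodes; type <- rep(0L, 8); branch <- rep(0L, 8)
  dof0 <- 3L * (nodes - 1L)
  # shifted Heaviside bases vanish identically on uncut elements (all nodes
  # share the element's side), so they only enter cut elements
  jn <- if (enr$elem_class[e] == "cut") nodes[enr$a_index[nodes] > 0]
        else integer(0)
  if (length(jn) > 0) {
    node <- c(node, jn); type <- c(type, rep(1L, length(jn)))
    branch <- c(branch, rep(0L, length(jn)))
    dof0 <- c(dof0, enr$a_dof0 + 3L * (enr$a_index[jn] - 1L))
  }
  mn <- nodes[enr$m_index[nodes] > 0]
  if (length(mn) > 0) {
    for (l in 1:4) {
      node <- c(node, mn); type <- c(type, rep(2L, length(mn)))
      branch <- c(branch, rep(l, length(mn)))
      dof0 <- c(dof0, enr$b_dof0 + 12L * (enr$m_index[mn] - 1L) + 3L * (l - 1L))
    }
  }
  list(node = node, type = type, branch = branch, dof0 = dof0)
}
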