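#' Boundary-condition set for the retraction solve
#'
#' Two families of displacement boundary conditions, mirroring the surgical
#' setting: a zero-displacement node set (the brain stem, where the tissue
#' is anchored) and prescribed crack-face displacements for the
#' retractor-contact nodes (per face, i.e. per sign of the crack level set
#' `phi`).
#'
#' @param fixed_nodes integer node ids clamped to zero displacement (their
#'   enriched DOFs, if any, are clamped too, pinning both crack faces).
#' @param crack_face_bcs data.frame with columns `node`, `face` (+1/-1) and
#'   `ux`, `uy`, `uz` (mm): the prescribed displacement of that node's
#'   crack face.
#' @return object of class `bc_set`.
#' @export
bc_set <- function(fixed_nodes = integer(),
                   crack_face_bcs = data.frame(node = integer(),
                                               face = integer(),
                                               ux = numeric(), uy = numeric(),
                                               uz = numeric())) {
  stopifnot(is.data.frame(crack_face_bcs),
            all(c("node", "face", "ux", "uy", "uz") %in% names(crack_face_bcs)))
  if (any(!crack_face_bcs$face %in% c(-1, 1)))
    stop("crack-face sign must be +1 or -1")
  both <- intersect(fixed_nodes, crack_face_bcs$node)
  if (length(both) > 0)
    stop("node(s) ", paste(both, collapse = ", "),
         " are both fixed and crack-prescribed")
  structure(list(fixed_nodes = as.integer(fixed_nodes),
                 crack_face_bcs = crack_face_bcs),
            class = "bc_set")
}

#' @export
print.bc_set <- function(x, ...) {
  cat(sprintf("<bc_set> %d fixed nodes, %d crack-face prescriptions (%d nodes)\n",
              length(x$fixed_nodes), nrow(x$crack_face_bcs),
              length(unique(x$crack_face_bcs$node))))
  invisible(x)
}

# Translate a bc_set into prescribed DOF indices (1-based) and target values.
# Under the shifted Heaviside basis the value on the face carrying the node
# (side s_j = H_j) is u_j and on the opposite face u_j - 2 s_j a_j, so
# prescribing faces (u+, u-) is exactly u_j = u^{s_j}, a_j = (u+ - u-) / 2.
prescribed_dofs <- function(enr, bcs) {
  idx <- integer(0); val <- numeric(0)
  n <- nrow(enr$mesh$nodes)
  if (any(bcs$fixed_nodes < 1 | bcs$fixed_nodes > n))
    stop("fixed node id out of range")
  for (nd in bcs$fixed_nodes) {
    idx <- c(idx, 3 * (nd - 1) + 1:3)
    if (enr$a_index[nd] > 0)
      idx <- c(idx, enr$a_dof0 + 3 * (enr$a_index[nd] - 1) + 1:3)
    if (enr$m_index[nd] > 0)
      idx <- c(idx, enr$b_dof0 + 12 * (enr$m_index[nd] - 1) + 1:12)
  }
  val <- c(val, numeric(length(idx)))
  cf <- bcs$crack_face_bcs
  if (nrow(cf) > 0) {
    if (any(cf$node < 1 | cf$node > n)) stop("crack-face node id out of range")
    for (nd in unique(cf$node)) {
      rows <- cf[cf$node == nd, , drop = FALSE]
      if (enr$a_index[nd] == 0) {
        # unenriched node: a single displacement, face tag informational
        if (nrow(rows) > 1 &&
            max(dist(as.matrix(rows[, c("ux", "uy", "uz")]))) > 1e-9)
          stop("node ", nd, " is not Heaviside-enriched but has conflicting ",
               "face displacements")
        idx <- c(idx, 3 * (nd - 1) + 1:3)
        val <- c(val, as.numeric(rows[1, c("ux", "uy", "uz")]))
      } else {
        if (!all(c(-1, 1) %in% rows$face))
          stop("Heaviside-enriched node ", nd,
               " needs prescribed displacements on both crack faces")
        up <- as.numeric(rows[match(1, rows$face), c("ux", "uy", "uz")])
        um <- as.numeric(rows[match(-1, rows$face), c("ux", "uy", "uz")])
        sj <- enr$H_node[nd]
        uj <- if (sj > 0) up else um
        aj <- (up - um) / 2
        idx <- c(idx, 3 * (nd - 1) + 1:3,
                 enr$a_dof0 + 3 * (enr$a_index[nd] - 1) + 1:3)
        val <- c(val, uj, aj)
      }
    }
  }
  dup <- duplicated(idx)
  list(idx = idx[!dup], val = val[!dup])
}

#' Solve the displacement-driven retraction problem
#'
#' Newton iteration on the hyper-viscoelastic XFEM equilibrium equations.
#' The prescribed displacements are ramped linearly over `increments` pseudo-
#' time steps spanning `duration` seconds (`duration = 0` gives the
#' instantaneous hyperelastic response); prescribed DOFs are imposed by
#' elimination and satisfied exactly.
#'
#' @param idata an [integration_data()] object.
#' @param bcs a [bc_set()]; both BC families are required for a unique
#'   solution unless `allow_no_fixed = TRUE`.
#' @param duration total loading pseudo-time, s.
#' @param increments number of load increments.
#' @param rtol,atol relative/absolute residual-norm convergence tolerances.
#' @param max_iter maximum Newton iterations per increment.
#' @param newton_refresh quasi-Newton tangent reuse: the consistent tangent
#'   is refactorised at the start of each increment and after this many
#'   reused iterations (or earlier when convergence stalls); `1` gives full
#'   Newton.
#' @param verbose print per-iteration residual norms.
#' @param allow_no_fixed skip the zero-displacement-BC sanity check (for
#'   fully prescribed-boundary problems such as patch tests).
#' @return object of class `displacement_field`: `dofs`, final material
#'   `state`, convergence `log` (data.frame), `energy` (final strain
#'   energy), plus the `enr` and `material` used.
#' @export
solve_retraction <- function(idata, bcs, duration = 30, increments = 10L,
                             rtol = 1e-6, atol = 1e-10, max_iter = 60L,
                             newton_refresh = 12L, verbose = FALSE,
                             allow_no_fixed = FALSE) {
  enr <- idata$enr
  pres <- prescribed_dofs(enr, bcs)
  if (length(pres$idx) == 0)
    stop("singular system: no prescribed DOFs at all")
  if (length(bcs$fixed_nodes) == 0 && !allow_no_fixed)
    stop("missing zero-displacement BCs")
  ndof <- idata$ndof
  free <- setdiff(seq_len(ndof), pres$idx)
  d <- numeric(ndof)
  state <- fresh_state(idata$material, idata$n_gp)
  dt <- if (increments > 0) duration / increments else 0
  log <- list()
  energy <- 0
  llt <- function(A) {
    notpd <- FALSE
    f <- tryCatch(
      withCallingHandlers(
        Matrix::Cholesky(A, LDL = FALSE, super = TRUE),
        warning = function(w) {
          if (grepl("not positive definite", conditionMessage(w)))
            notpd <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (notpd) NULL else f
  }
  # Shift ladder for indefinite tangents: the consistent tangent can lose
  # positive definiteness at large strain; a diagonal shift restores a
  # usable descent direction (the line search guards the step). The level
  # that last worked is remembered and reused, because every failed
  # supernodal attempt is expensive (and Matrix/CHOLMOD does not return all
  # native memory of a failed factorisation). Simplicial LDL is avoided:
  # on systems of this size it is an order of magnitude slower.
  shift_ladder <- c(0, 1e-6, 1e-4, 1e-2, 1)
  shift_level <- 1L
  factorise <- function(K) {
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    s0 <- mean(abs(Matrix::diag(Kff)))
    f <- NULL
    # probe one level below the remembered shift so the level can recover
    # as the iterate approaches equilibrium (at most one failing attempt)
    for (lev in max(1L, shift_level - 1L):length(shift_ladder)) {
      gc(verbose = FALSE)
      f <- if (shift_ladder[lev] == 0) llt(Kff)
           else llt(Kff + shift_ladder[lev] * s0 *
                      Matrix::Diagonal(nrow(Kff)))
      if (!is.null(f)) { shift_level <<- lev; break }
    }
    if (is.null(f))
      f <- tryCatch(Matrix::lu(Kff),
                    error = function(e) stop("singular-system error ",
                                             "(insufficient BCs?): ",
                                             conditionMessage(e)))
    f
  }
  for (inc in seq_len(increments)) {
    # Factorise at the previous converged state, before the boundary bump:
    # there the tangent is that of a stable equilibrium (positive definite
    # in practice), whereas the freshly bumped state often is not.
    fact <- NULL
    gc(verbose = FALSE)
    fact <- factorise(assemble_system(idata, d, state, dt,
                                      tangent = TRUE)$K)
    gc(verbose = FALSE)
    ramp <- inc / increments
    d[pres$idx] <- ramp * pres$val
    out <- assemble_system(idata, d, state, dt, tangent = FALSE)
    stale <- 0L
    ref <- NA_real_
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      rf <- out$resid[free]
      rn <- sqrt(sum(rf^2))
      if (is.na(ref)) ref <- max(rn, atol)
      log[[length(log) + 1]] <- data.frame(increment = inc, iter = it - 1L,
                                           resid = rn)
      if (verbose)
        message(sprintf("inc %d it %d |r| = %.3e", inc, it - 1L, rn))
      if (rn <= max(rtol * ref, atol)) { converged <- TRUE; break }
      # quasi-Newton: refresh the consistent tangent only when convergence
      # stalls badly (the refreshed tangent at a non-equilibrium state may
      # be indefinite and need the shift ladder)
      if (is.null(fact) || stale >= newton_refresh) {
        # drop the previous factor before building a new one: CHOLMOD
        # factors live outside the R heap, so an explicit collection is
        # needed to keep long solves from accumulating native memory
        fact <- NULL
        gc(verbose = FALSE)
        fact <- factorise(assemble_system(idata, d, state, dt,
                                          tangent = TRUE)$K)
        gc(verbose = FALSE)   # release the assembly/ladder transients
        stale <- 0L
      }
      du <- as.numeric(Matrix::solve(fact, -rf))
      # backtracking line search on the residual norm
      alpha <- 1
      repeat {
        d_try <- d
        d_try[free] <- d[free] + alpha * du
        out_try <- tryCatch(
          assemble_system(idata, d_try, state, dt, tangent = FALSE),
          error = function(e) NULL)
        if (!is.null(out_try)) {
          rn_try <- sqrt(sum(out_try$resid[free]^2))
          if (rn_try < rn || alpha <= 1 / 16) break
        }
        alpha <- alpha / 2
        if (alpha < 1 / 64)
          stop("line search failed in increment ", inc)
      }
      # count a stall (barely reduced residual) heavily towards a refresh
      stale <- stale + if (rn_try > 0.9 * rn) 4L else 1L
      d <- d_try
      out <- out_try
    }
    if (!converged) {
      rn_final <- sqrt(sum(out$resid[free]^2))
      stop(sprintf(paste0("Newton did not converge in increment %d after %d ",
                          "iterations (|r| = %.3e, target %.3e)"),
                   inc, max_iter, rn_final, max(rtol * ref, atol)))
    }
    state <- out$state           # commit viscoelastic history
    energy <- out$energy
    fact <- NULL
    gc(verbose = FALSE)
  }
  structure(list(enr = enr, material = idata$material, dofs = d,
                 state = state, log = do.call(rbind, log), energy = energy,
                 duration = duration, increments = increments),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  umag <- sqrt(rowSums(matrix(x$dofs[seq_len(3 * nrow(x$enr$mesh$nodes))],
                              ncol = 3, byrow = TRUE)^2))
  cat(sprintf(paste0("<displacement_field> %d DOFs, %d increments over %g s; ",
                     "max |u| at nodes = %.3f mm; strain energy %.4g\n"),
              length(x$dofs), x$increments, x$duration, max(umag), x$energy))
  invisible(x)
}

#' Nodal displacements of a solved field
#'
#' @param field a `displacement_field`.
#' @return `n x 3` matrix of standard nodal displacements, mm.
#' @export
nodal_displacements <- function(field) {
  n <- nrow(field$enr$mesh$nodes)
  matrix(field$dofs[seq_len(3 * n)], ncol = 3, byrow = TRUE)
}
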