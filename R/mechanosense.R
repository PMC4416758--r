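# Effective mechanical parameters of a phenotype: sigma_max scaled by the
# phenotype contractility factor; everything else shared.
effective_params <- function(p, fac) {
  if (fac == 1) return(p)
  q <- unclass(p)
  q$sigma_max <- q$sigma_max * fac
  structure(q, class = "mechanical_params")
}

# World positions of the membrane nodes of a cell.
membrane_points <- function(cell, p) {
  sweep(p$r_cell * cell$membrane_dirs, 2L, cell$centroid, `+`)
}

#' Mechano-sensing of the substrate by one cell
#'
#' The cell exerts contractile sensing forces of magnitude
#' \code{cell_stress(-eps_i) * S_node} at every active membrane node,
#' directed toward its centroid; the substrate deforms; the internal
#' deformation at node i is the contraction ratio MN/OM, i.e. the nodal
#' displacement projected on the inward direction divided by the cell
#' radius. Force magnitude and deformation are mutually consistent: the
#' self-consistent state is found exactly by building the 24 x 24
#' influence matrix of the factorized substrate operator (one multi-RHS
#' solve) and solving the piecewise-linear coupled system by an
#' active-set iteration over the stress-law branches. Contact-suppressed
#' (inactive) nodes exert no sensing force but their substrate strain is
#' still recorded.
#'
#' @param cell a \code{cell_state}.
#' @param op an \code{fe_operator}.
#' @param p a \code{mechanical_params}.
#' @param fp a \code{fate_params} (phenotype contractility); NULL for the
#'   progenitor default.
#' @return the cell with updated \code{node_strain} (unsigned contraction
#'   ratio, positive inward), \code{node_tensor} (substrate strain tensors
#'   at the node positions) and attribute fields \code{sense_converged},
#'   \code{sense_iters}, \code{node_stress} (kPa).
#' @export
mechanosense <- function(cell, op, p = mechanical_params(), fp = NULL) {
  fac <- if (is.null(fp)) 1 else contractility_factor(cell$phenotype, fp)
  pe <- effective_params(p, fac)
  n <- cell$membrane_dirs
  nm <- nrow(n)
  pts <- membrane_points(cell, p)
  pw <- point_weights(op$mesh, pts)
  S <- node_area(p)
  act <- cell$node_active

  # Influence matrix: column j = response to a unit (1 nN) inward force
  # at node j; row i = contraction ratio at node i per unit force.
  B <- matrix(0, op$n_dof, nm)
  for (j in seq_len(nm)) {
    dofs <- rep(3L * (pw$nodes[j, ] - 1L), each = 3L) + rep(1:3, times = 8L)
    B[dofs, j] <- B[dofs, j] + as.vector(t(pw$w[j, ] %o% (-n[j, ])))
  }
  X <- matrix(0, op$n_dof, nm)
  X[op$free, ] <- as.matrix(Matrix::solve(op$chol, B[op$free, , drop = FALSE],
                                          system = "A"))
  M <- matrix(0, nm, nm)
  for (i in seq_len(nm)) {
    dofs <- rep(3L * (pw$nodes[i, ] - 1L), each = 3L) + rep(1:3, times = 8L)
    wdir <- as.vector(t(pw$w[i, ] %o% (-n[i, ])))
    M[i, ] <- (wdir %*% X[dofs, , drop = FALSE]) / p$r_cell
  }

  # Active-set solve of eps = M %*% f, f = S * sigma(-eps) on active
  # nodes, f = 0 on contact-suppressed nodes.
  eps <- rep(0, nm)
  converged <- FALSE
  iters <- 0L
  Ma <- M[, act, drop = FALSE]
  for (it in seq_len(50L)) {
    iters <- it
    br <- stress_branches(-eps[act], pe)
    # sigma(-eps) = a - b * eps on the current branches, so
    # (I + S * M[, act] diag(b) P_act) eps = S * M[, act] a
    A <- diag(nm)
    A[, act] <- A[, act] + S * sweep(Ma, 2L, br$b, `*`)
    eps_new <- solve(A, S * (Ma %*% br$a))
    same <- all(stress_branches(-eps_new[act], pe)$a == br$a)
    delta <- max(abs(eps_new - eps))
    eps <- as.numeric(eps_new)
    if (same || delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("mechanosense: branch assignment did not settle after 50 iterations; ",
            "using last iterate", call. = FALSE)
  }

  sigma <- numeric(nm)
  bra <- stress_branches(-eps[act], pe)
  sigma[act] <- bra$a - bra$b * eps[act]
  f <- ifelse(act, S * sigma, 0)

  u <- matrix(0, op$mesh$n_nodes, 3L)
  uf <- X %*% f
  u[, 1] <- uf[seq(1, op$n_dof, by = 3L)]
  u[, 2] <- uf[seq(2, op$n_dof, by = 3L)]
  u[, 3] <- uf[seq(3, op$n_dof, by = 3L)]

  cell$node_strain <- eps
  cell$node_tensor <- strain_at_points(op$mesh, u, pts, pw$loc)
  cell$node_stress <- sigma
  cell$sense_converged <- converged
  cell$sense_iters <- iters
  cell
}
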