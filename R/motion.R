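# Stokes drag coefficient in simulator units: force nN, speed um/h.
# 6*pi*r*eta with r in um and eta in Pa s gives Pa s um; 1 Pa um^2 =
# 1e-3 nN and 1 h = 3600 s, hence the single conversion factor.
drag_coefficient <- function(r_cell, eta) {
  6 * pi * r_cell * eta * 1e-3 / 3600
}

#' Traction forces of a cell
#'
#' Per-node traction magnitude \code{cell_stress(-eps_i) * S_node *
#' zeta_rel_i}, acting on the cell along the outward node direction (the
#' cell pulls itself toward each adhesion; the reaction on the substrate
#' points inward). Relative adhesivity is the front/back adhesivity
#' ratio: nodes whose outward direction has non-negative projection on
#' the previous polarisation use the front value
#' \code{k_f n_rf / (k_b n_rb)} (1.5 with reference receptor numbers),
#' the rest 1. On the first step (no polarisation yet) all nodes use the
#' front value. Contact-suppressed nodes still carry traction.
#'
#' @param cell a \code{cell_state} with populated \code{node_strain}.
#' @param p a \code{mechanical_params}.
#' @param e_pol_prev previous polarisation unit vector, or NULL.
#' @param fp optional \code{fate_params} for phenotype contractility.
#' @return list with \code{forces} (n_mem x 3, nN) and \code{net}
#'   (length-3 vector, nN).
#' @export
traction_forces <- function(cell, p = mechanical_params(), e_pol_prev = NULL,
                            fp = NULL) {
  fac <- if (is.null(fp)) 1 else contractility_factor(cell$phenotype, fp)
  pe <- effective_params(p, fac)
  n <- cell$membrane_dirs
  sigma <- cell_stress(-cell$node_strain, pe)
  zeta_front <- adhesivity(p$k_f, p$n_rf, p$psi)
  zeta_back <- adhesivity(p$k_b, p$n_rb, p$psi)
  zr <- rep(zeta_front / zeta_back, nrow(n))
  if (!is.null(e_pol_prev)) {
    zr[as.vector(n %*% e_pol_prev) < 0] <- 1
  }
  forces <- (sigma * node_area(p) * zr) * n
  list(forces = forces, net = colSums(forces))
}

#' Random protrusion force
#'
#' Exploratory force from actin polymerization: magnitude a uniform
#' [0, 1) fraction of the net traction magnitude, direction uniform on
#' the unit sphere. Draws two variates from the current RNG stream in a
#' fixed order (kappa, then the direction).
#'
#' @param F_trac_net net traction force vector (nN).
#' @return length-3 protrusion force (nN).
#' @export
protrusion_force <- function(F_trac_net) {
  kappa <- stats::runif(1)
  d <- stats::rnorm(3)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) d <- c(1, 0, 0) else d <- d / nrm
  kappa * sqrt(sum(F_trac_net^2)) * d
}

#' Force balance, polarisation, velocity and translocation
#'
#' Inertia is negligible at cell scale, so the drag force closes the
#' balance exactly: \code{F_drag = -(F_trac_net + F_prot)}. The cell
#' polarises against the drag, moves at the Stokes speed
#' \code{|F_drag| / (6 pi r eta)} and translocates \code{v * tau} along
#' the polarisation. A zero drag force leaves the previous polarisation
#' in place and produces no translocation.
#'
#' @param F_trac_net net traction (nN).
#' @param F_prot protrusion force (nN).
#' @param p a \code{mechanical_params}.
#' @param mat a \code{material_props} (viscosity).
#' @param e_pol_prev previous polarisation (kept if the drag vanishes).
#' @return list of class \code{force_balance}: \code{F_trac_net},
#'   \code{F_prot}, \code{F_drag} (nN), \code{e_pol}, \code{v} (um/h),
#'   \code{d} (um).
#' @export
resolve_motion <- function(F_trac_net, F_prot, p = mechanical_params(),
                           mat, e_pol_prev = NULL) {
  F_drag <- -(F_trac_net + F_prot)
  nrm <- sqrt(sum(F_drag^2))
  if (nrm > 0) {
    e_pol <- -F_drag / nrm
    v <- nrm / drag_coefficient(p$r_cell, mat$eta)
    d <- v * p$tau * e_pol
  } else {
    e_pol <- e_pol_prev
    v <- 0
    d <- c(0, 0, 0)
  }
  structure(list(F_trac_net = F_trac_net, F_prot = F_prot, F_drag = F_drag,
                 e_pol = e_pol, v = v, d = d), class = "force_balance")
}
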