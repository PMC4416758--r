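#' Cell stress transmitted to the substrate
#'
#' Piecewise-linear active + passive stress law of the contractile
#' apparatus. Outside the working strain range \code{[eps_min, eps_max]}
#' only the passive elements (microtubules, membrane) act,
#' \code{sigma = K_pas * eps}. Inside, the actin-myosin active stress
#' rises linearly from zero at \code{eps_min} to \code{sigma_max} at
#' \code{eps_tilde = sigma_max / K_act}, then falls back to zero at
#' \code{eps_max} (a tent-shaped length-tension curve), superposed on the
#' passive line. The law is continuous at all three breakpoints.
#'
#' Sign convention: \code{eps} is the signed axial strain of the cell,
#' negative in contraction (compression). The mechano-sensing loop stores
#' the unsigned contraction ratio MN/OM and evaluates this law at its
#' negative.
#'
#' @param eps signed internal strain (dimensionless), vectorised.
#' @param p a \code{mechanical_params}.
#' @return stress in kPa.
#' @examples
#' p <- mechanical_params()
#' cell_stress(1.0, p)   # outside the working range: 2.8 * 1.0
#' cell_stress(0, p)     # ~ 0.0947
#' cell_stress(0.05, p)  # peak active stress: 0.1 + 2.8 * 0.05
#' @export
cell_stress <- function(eps, p = mechanical_params()) {
  br <- stress_branches(eps, p)
  br$a + br$b * eps
}

# Branch coefficients of sigma(eps) = a + b * eps for each entry of eps.
# Used by cell_stress() and by the exact piecewise-linear sensing solve.
stress_branches <- function(eps, p) {
  et <- p$sigma_max / p$K_act
  a <- numeric(length(eps))
  b <- rep(p$K_pas, length(eps))
  den_lo <- p$K_act * p$eps_min - p$sigma_max
  den_hi <- p$K_act * p$eps_max - p$sigma_max
  lo <- eps >= p$eps_min & eps <= et
  hi <- eps > et & eps <= p$eps_max
  a[lo] <- p$K_act * p$sigma_max * p$eps_min / den_lo
  b[lo] <- b[lo] - p$K_act * p$sigma_max / den_lo
  a[hi] <- p$K_act * p$sigma_max * p$eps_max / den_hi
  b[hi] <- b[hi] - p$K_act * p$sigma_max / den_hi
  list(a = a, b = b)
}

#' Adhesivity
#'
#' Dimensionless product of the integrin binding constant, the number of
#' available receptors and the ligand concentration,
#' \code{zeta = k * n_r * psi}. The traction law uses the front/back
#' ratio of this quantity (relative adhesivity), so only the asymmetry
#' between the leading and trailing halves of the membrane matters.
#'
#' @param k binding constant (1/mol).
#' @param n_r number of available receptors.
#' @param psi ligand concentration (mol).
#' @return adhesivity (dimensionless).
#' @examples
#' adhesivity(1e8, 1.5e5, 1e-5)  # front: 1.5e8
#' adhesivity(1e8, 1e5, 1e-5)    # back:  1.0e8
#' @export
adhesivity <- function(k, n_r, psi) k * n_r * psi

# Per-node membrane area (um^2): equal partition of the spherical
# membrane over the node template.
node_area <- function(p) 4 * pi * p$r_cell^2 / p$n_mem

# sigma_max multiplier for a phenotype.
contractility_factor <- function(phenotype, fp) {
  unname(fp$contractility[phenotype])
}
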