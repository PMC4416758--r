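#' Cell mechanical parameters
#'
#' Container for the mechanical constants of the cell agent. Defaults are
#' the reference parameter set used throughout: passive (microtubule)
#' stiffness 2.8 kPa, active (myosin II) stiffness 2 kPa, strain bounds
#' -0.9/0.9, maximum contractile stress 0.1 kPa, integrin binding constant
#' 1e8 / mol, 1.5e5 receptors at the cell front and 1e5 at the rear,
#' ligand concentration 1e-5 mol, time step 6 h. The cell radius (20 um)
#' and membrane node count (24) complete the spherical cell geometry;
#' neither is part of the reference table, the radius is a configurable
#' geometric default consistent with the 10 um substrate element size.
#'
#' \code{eps_tilde = sigma_max / K_act} (strain of peak active stress) is
#' derived, not stored.
#'
#' @param K_pas passive stiffness (kPa).
#' @param K_act active stiffness (kPa).
#' @param eps_min,eps_max internal strain bounds (dimensionless).
#' @param sigma_max maximum actin-myosin contractile stress (kPa).
#' @param k_f,k_b integrin binding constants, front/back (1/mol).
#' @param n_rf,n_rb available receptor counts, front/back.
#' @param psi ligand concentration (mol).
#' @param r_cell cell radius (um).
#' @param n_mem number of membrane nodes.
#' @param tau time step (h).
#' @return object of class \code{mechanical_params}.
#' @export
mechanical_params <- function(K_pas = 2.8, K_act = 2, eps_min = -0.9,
                              eps_max = 0.9, sigma_max = 0.1,
                              k_f = 1e8, k_b = 1e8, n_rf = 1.5e5, n_rb = 1e5,
                              psi = 1e-5, r_cell = 20, n_mem = 24L, tau = 6) {
  p <- list(K_pas = K_pas, K_act = K_act, eps_min = eps_min, eps_max = eps_max,
            sigma_max = sigma_max, k_f = k_f, k_b = k_b, n_rf = n_rf,
            n_rb = n_rb, psi = psi, r_cell = r_cell, n_mem = as.integer(n_mem),
            tau = tau)
  eps_tilde <- sigma_max / K_act
  if (!(eps_min < 0 && 0 < eps_tilde && eps_tilde < eps_max)) {
    stop("invalid config: need eps_min < 0 < sigma_max/K_act < eps_max",
         call. = FALSE)
  }
  if (r_cell <= 0) stop("invalid config: r_cell must be > 0", call. = FALSE)
  if (p$n_mem < 4L) stop("invalid config: n_mem must be >= 4", call. = FALSE)
  if (tau <= 0) stop("invalid config: tau must be > 0", call. = FALSE)
  structure(p, class = "mechanical_params")
}

#' Cell fate parameters
#'
#' Thresholds of the mechanical signal gamma that partition cell fate,
#' and the maturation time constants. Defaults are the reference set:
#' osteoblast band (gamma_l, gamma_s] = (0.005, 0.04], chondrocyte band
#' (gamma_s, gamma_c] = (0.04, 0.1], neuroblast band (gamma_c, gamma_u] =
#' (0.1, 0.5], apoptosis above gamma_apop = 1; minimum maturation time
#' t_min = 4 days and time proportionality t_p = 200 days. The MSC
#' proliferation limit is 0.2; limits for the differentiated phenotypes
#' are not part of the reference table and default to the same value.
#'
#' \code{contractility} gives per-phenotype multipliers of
#' \code{sigma_max}: committed osteoblasts and chondrocytes are more
#' contractile than the progenitor MSC, neuroblasts markedly less. These
#' factors produce the characteristic traction change at differentiation
#' (increase for osteogenic/chondrogenic, decrease for neurogenic
#' commitment).
#'
#' \code{concurrent} selects what happens when a mature MSC satisfies the
#' differentiation and proliferation conditions in the same step:
#' \code{"divide_differentiated"} (default; division occurs and both
#' daughters carry the new phenotype), \code{"differentiate_only"}, or
#' \code{"coin_flip"} (50/50 between the two).
#'
#' @param t_min minimum maturation time (days).
#' @param t_p maturation time proportionality (days).
#' @param gamma_l,gamma_s,gamma_c,gamma_u differentiation band edges.
#' @param gamma_apop apoptosis threshold.
#' @param gamma_prof named numeric, per-phenotype proliferation limits.
#' @param contractility named numeric, per-phenotype sigma_max multipliers.
#' @param concurrent concurrency rule, see Details.
#' @return object of class \code{fate_params}.
#' @export
fate_params <- function(t_min = 4, t_p = 200,
                        gamma_l = 0.005, gamma_s = 0.04, gamma_c = 0.1,
                        gamma_u = 0.5, gamma_apop = 1,
                        gamma_prof = c(MSC = 0.2, osteoblast = 0.2,
                                       chondrocyte = 0.2, neuroblast = 0.2),
                        contractility = c(MSC = 1, osteoblast = 1.5,
                                          chondrocyte = 1.25, neuroblast = 0.6),
                        concurrent = c("divide_differentiated",
                                       "differentiate_only", "coin_flip")) {
  concurrent <- match.arg(concurrent)
  if (!(gamma_l < gamma_s && gamma_s < gamma_c && gamma_c < gamma_u &&
        gamma_u <= gamma_apop)) {
    stop("invalid config: need gamma_l < gamma_s < gamma_c < gamma_u <= gamma_apop",
         call. = FALSE)
  }
  if (t_min <= 0) stop("invalid config: t_min must be > 0", call. = FALSE)
  need <- c("MSC", "osteoblast", "chondrocyte", "neuroblast")
  if (!all(need %in% names(gamma_prof))) {
    stop("invalid config: gamma_prof must name all four phenotypes", call. = FALSE)
  }
  if (any(gamma_prof >= gamma_u)) {
    stop("invalid config: proliferation limits must satisfy gamma_prof < gamma_u",
         call. = FALSE)
  }
  if (!all(need %in% names(contractility))) {
    stop("invalid config: contractility must name all four phenotypes", call. = FALSE)
  }
  structure(list(t_min = t_min, t_p = t_p, gamma_l = gamma_l, gamma_s = gamma_s,
                 gamma_c = gamma_c, gamma_u = gamma_u, gamma_apop = gamma_apop,
                 gamma_prof = gamma_prof[need], contractility = contractility[need],
                 concurrent = concurrent),
            class = "fate_params")
}

PHENOTYPES <- c("MSC", "osteoblast", "chondrocyte", "neuroblast")

#' Create a cell agent
#'
#' @param id integer cell id.
#' @param centroid position (um).
#' @param phenotype one of MSC, osteoblast, chondrocyte, neuroblast.
#' @param params a \code{mechanical_params}.
#' @param MI initial maturation index in [0, 1].
#' @param e_pol initial polarisation direction (unit vector) or NULL.
#' @return object of class \code{cell_state}.
#' @export
cell_state <- function(id, centroid, phenotype = "MSC",
                       params = mechanical_params(), MI = 0, e_pol = NULL) {
  if (!phenotype %in% PHENOTYPES) {
    stop("invalid state: unknown phenotype '", phenotype, "'", call. = FALSE)
  }
  if (MI < 0 || MI > 1) stop("invalid state: MI must lie in [0,1]", call. = FALSE)
  n <- membrane_template(params$n_mem)
  structure(list(
    id = as.integer(id), phenotype = phenotype,
    centroid = as.numeric(centroid),
    membrane_dirs = n,
    node_active = rep(TRUE, params$n_mem),
    node_strain = rep(0, params$n_mem),
    node_tensor = array(0, c(params$n_mem, 3L, 3L)),
    MI = MI, age_in_phenotype = 0, alive = TRUE,
    e_pol = e_pol, gamma = 0, F_trac_net = c(0, 0, 0), v = 0
  ), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("cell %d [%s] at (%.1f, %.1f, %.1f) um, MI = %.3f, gamma = %.4f\n",
              x$id, x$phenotype, x$centroid[1], x$centroid[2], x$centroid[3],
              x$MI, x$gamma))
  invisible(x)
}
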