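#' Mechanical signal of a cell
#'
#' Sum over all membrane nodes of the substrate strain tensor projected
#' twice onto the polarisation direction, \code{sum_i e_pol' eps_i e_pol}.
#' Under contraction the sum is negative with the usual continuum sign
#' convention while the fate thresholds are positive, so the absolute
#' value is returned. Contact-suppressed nodes contribute their stored
#' substrate strain.
#'
#' @param node_tensors n_mem x 3 x 3 array of strain tensors.
#' @param e_pol polarisation unit vector.
#' @return gamma (dimensionless, >= 0).
#' @export
mechanical_signal <- function(node_tensors, e_pol) {
  stopifnot(abs(sqrt(sum(e_pol^2)) - 1) < 1e-8)
  n <- dim(node_tensors)[1]
  g <- 0
  for (i in seq_len(n)) {
    g <- g + as.numeric(e_pol %*% node_tensors[i, , ] %*% e_pol)
  }
  abs(g)
}

#' Maturation time
#'
#' Linear dependence of the maturation period on the mechanical signal:
#' \code{t_mat = t_min + t_p * gamma}. Stronger mechanical signal
#' strength (smaller internal deformation, i.e. stiffer substrate)
#' shortens maturation down to the floor \code{t_min}.
#'
#' @param gamma mechanical signal (>= 0).
#' @param fp a \code{fate_params}.
#' @return maturation time in days.
#' @examples
#' maturation_time(0, fate_params())       # 4
#' maturation_time(0.0075, fate_params())  # 5.5
#' @export
maturation_time <- function(gamma, fp = fate_params()) {
  stopifnot(all(gamma >= 0))
  fp$t_min + fp$t_p * gamma
}

#' Advance the maturation index of a cell
#'
#' The maturation index accrues incrementally,
#' \code{dMI = tau / t_mat(gamma(t))}, capped at 1. For constant gamma
#' this reduces exactly to the ratio form MI = t / t_mat; with a
#' time-varying signal the accrual keeps MI non-decreasing
#' (irreversibility), while the instantaneous maturation time may rise
#' or fall with the signal. MI resets to 0 only on phenotype change.
#'
#' @param MI current maturation index in [0, 1].
#' @param gamma current mechanical signal.
#' @param tau_h time step in hours.
#' @param fp a \code{fate_params}.
#' @return updated MI.
#' @export
update_MI <- function(MI, gamma, tau_h, fp = fate_params()) {
  stopifnot(MI >= 0, MI <= 1)
  min(1, MI + (tau_h / 24) / maturation_time(gamma, fp))
}

#' Fate decision of a cell
#'
#' Applies the mechano-regulated fate rules: apoptosis whenever the
#' signal exceeds \code{gamma_apop}, regardless of maturity; otherwise a
#' fully mature MSC commits to the lineage whose half-open signal band
#' contains gamma (osteoblast, chondrocyte or neuroblast; committed
#' phenotypes never re-differentiate); any fully mature cell whose
#' signal is at or below its proliferation limit divides. When a mature
#' MSC satisfies both conditions the processes occur congruently
#' according to the concurrency rule in \code{fate_params}.
#'
#' @param cell a \code{cell_state}.
#' @param gamma mechanical signal.
#' @param fp a \code{fate_params}.
#' @return list with logical \code{apoptosis}, \code{proliferate}, and
#'   \code{differentiate} (target phenotype or NA).
#' @export
decide_fate <- function(cell, gamma, fp = fate_params()) {
  if (!cell$alive) stop("invalid state: fate decision for a dead cell", call. = FALSE)
  if (!cell$phenotype %in% PHENOTYPES) {
    stop("invalid state: unknown phenotype '", cell$phenotype, "'", call. = FALSE)
  }
  if (gamma > fp$gamma_apop) {
    return(list(apoptosis = TRUE, proliferate = FALSE, differentiate = NA_character_))
  }
  target <- NA_character_
  if (cell$MI >= 1 && cell$phenotype == "MSC") {
    if (gamma > fp$gamma_l && gamma <= fp$gamma_s) target <- "osteoblast"
    else if (gamma > fp$gamma_s && gamma <= fp$gamma_c) target <- "chondrocyte"
    else if (gamma > fp$gamma_c && gamma <= fp$gamma_u) target <- "neuroblast"
  }
  prolif <- cell$MI >= 1 && gamma <= unname(fp$gamma_prof[cell$phenotype])
  if (!is.na(target) && prolif) {
    if (fp$concurrent == "differentiate_only") {
      prolif <- FALSE
    } else if (fp$concurrent == "coin_flip") {
      if (stats::runif(1) < 0.5) prolif <- FALSE else target <- NA_character_
    }
    # "divide_differentiated": both fire; daughters carry the new phenotype.
  }
  list(apoptosis = FALSE, proliferate = prolif, differentiate = target)
}

#' Place the daughters of a dividing cell
#'
#' One daughter keeps the mother's position; the other is placed one
#' cell diameter away along a random unit direction, redrawn (up to
#' \code{max_tries}) until it lies at least one radius inside the box
#' and at least one diameter from every other cell. Both daughters start
#' non-mature (MI = 0, age 0).
#'
#' @param mother a \code{cell_state} with MI = 1.
#' @param others list of other cells (for the separation constraint).
#' @param p a \code{mechanical_params}.
#' @param box box extents (um).
#' @param phenotype phenotype of the daughters (the mother's, or the
#'   differentiation target under a congruent event).
#' @param max_tries placement attempts before deferring.
#' @return list(daughter1, daughter2) or NULL if no admissible placement
#'   was found (proliferation deferred).
#' @export
apply_proliferation <- function(mother, others, p, box,
                                phenotype = mother$phenotype,
                                max_tries = 100L) {
  r <- p$r_cell
  pos2 <- NULL
  for (try in seq_len(max_tries)) {
    d <- stats::rnorm(3)
    e_rand <- d / sqrt(sum(d^2))
    cand <- mother$centroid + 2 * r * e_rand
    inside <- all(cand >= r) && all(cand <= box - r)
    clear <- TRUE
    for (oc in others) {
      if (oc$id != mother$id &&
          sqrt(sum((cand - oc$centroid)^2)) < 2 * r - 1e-9) {
        clear <- FALSE
        break
      }
    }
    if (inside && clear) { pos2 <- cand; break }
  }
  if (is.null(pos2)) return(NULL)
  d1 <- cell_state(NA_integer_, mother$centroid, phenotype, p, MI = 0,
                   e_pol = mother$e_pol)
  d2 <- cell_state(NA_integer_, pos2, phenotype, p, MI = 0,
                   e_pol = mother$e_pol)
  list(d1, d2)
}
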