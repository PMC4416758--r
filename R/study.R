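#' Run the six-stiffness desk-scale study
#'
#' Runs the soft (0.1, 1 kPa), intermediate (20, 25 kPa) and hard
#' (30, 45 kPa) scenarios with the reference cell parameters on a
#' desk-scale substrate that keeps the reference 10 um element size
#' (default 200 x 100 x 100 um, 20 x 10 x 10; the sensing near-field
#' that sets the mechanical signal scale is pinned to the element size,
#' so the box is shrunk rather than coarsened). Each scenario runs
#' \code{replicates} independently seeded replicates of a single
#' corner-seeded MSC and stops early once a differentiated cell has
#' proliferated (the latest event any summary quantity needs); soft
#' scenarios get longer horizons to cover their slower maturation.
#'
#' @param seed base seed; scenario k replicate j runs with
#'   \code{seed + 1000 * k + j}.
#' @param replicates replicates per scenario.
#' @param dims,n_div substrate geometry.
#' @param stiffnesses scenario moduli (kPa).
#' @param horizon_steps named vector of step horizons per stiffness;
#'   defaults: 140 steps (35 days) at or above 20 kPa, 480 (120 days) at
#'   1 kPa, 520 (130 days) at 0.1 kPa.
#' @param verbose print progress.
#' @return named list of \code{scenario_result} objects, one per
#'   stiffness.
#' @export
run_stiffness_study <- function(seed = 1L, replicates = 10L,
                                dims = c(200, 100, 100),
                                n_div = c(20, 10, 10),
                                stiffnesses = scenario_stiffnesses(),
                                horizon_steps = NULL,
                                verbose = TRUE) {
  if (is.null(horizon_steps)) {
    horizon_steps <- vapply(stiffnesses, function(E) {
      if (E >= 20) 140L else if (E >= 1) 480L else 520L
    }, integer(1))
    names(horizon_steps) <- as.character(stiffnesses)
  }
  stop_rule <- function(events, cells) {
    any(events$kind == "proliferation" & events$phenotype_before != "MSC")
  }
  mesh <- build_hex_mesh(dims, n_div)
  out <- vector("list", length(stiffnesses))
  names(out) <- as.character(stiffnesses)
  for (k in seq_along(stiffnesses)) {
    E <- stiffnesses[k]
    if (verbose) message(sprintf("scenario E = %g kPa ...", E))
    cfg <- scenario_config(E, dims = dims, n_div = n_div,
                           n_steps = horizon_steps[[as.character(E)]],
                           replicates = replicates,
                           seed = seed + 1000L * k,
                           stop_rule = stop_rule)
    op <- assemble_operator(mesh, cfg$mat)
    out[[k]] <- run_scenario(cfg, op = op)
  }
  out
}

#' Summary table of a stiffness study
#'
#' Cross-replicate means of the study's headline quantities per
#' scenario: time of first MSC maturation, first differentiation (with
#' its modal lineage), first proliferation by a differentiated cell and
#' first post-differentiation full maturation, all in days.
#'
#' @param study result of \code{run_stiffness_study}.
#' @return data.frame with one row per scenario.
#' @export
study_table <- function(study) {
  rows <- lapply(names(study), function(nm) {
    res <- study[[nm]]
    get_mean <- function(metric) {
      s <- res$summary
      s$mean[s$metric == metric]
    }
    reps <- res$replicates
    t_diff <- vapply(reps, function(r)
      first_event_time(r$events, "differentiation"), numeric(1))
    t_prol2 <- vapply(reps, function(r) {
      ev <- r$events
      sel <- ev$kind == "proliferation" & ev$phenotype_before != "MSC"
      if (!any(sel)) NA_real_ else min(ev$time_days[sel])
    }, numeric(1))
    t_mat2 <- vapply(reps, function(r) {
      ev <- r$events
      sel <- ev$kind == "matured" & ev$phenotype_before != "MSC"
      if (!any(sel)) NA_real_ else min(ev$time_days[sel])
    }, numeric(1))
    data.frame(
      E_kPa = as.numeric(nm),
      modal_lineage = modal_first_differentiation(res),
      t_matured_MSC = get_mean("t_first_matured"),
      t_first_diff = mean(t_diff, na.rm = TRUE),
      n_diff = sum(!is.na(t_diff)),
      t_first_prolif_diff = mean(t_prol2, na.rm = TRUE),
      n_prolif_diff = sum(!is.na(t_prol2)),
      t_matured_diff = mean(t_mat2, na.rm = TRUE),
      n_matured_diff = sum(!is.na(t_mat2)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
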