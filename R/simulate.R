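#' Simulation configuration
#'
#' Bundles substrate geometry, material, cell parameters, fate rules and
#' run control. The defaults reproduce the reference setup: a
#' 400 x 200 x 200 um substrate meshed 40 x 20 x 20 (16,000 hexahedra,
#' 18,081 nodes), one MSC seeded at the box corner one cell radius from
#' the three faces, a 6 h time step, and 20 replicates.
#'
#' \code{d_max} caps the translocation applied per step (um). It is a
#' numerical step limiter keeping the agent's sampling of the substrate
#' quasi-continuous: the force balance can produce Stokes speeds far
#' above the biological range, and an uncapped step would jump across
#' the whole box. The default, half a cell radius per step
#' (~1.7 um/h at tau = 6 h), is the typical 3D mesenchymal migration
#' speed scale.
#'
#' @param E substrate Young's modulus (kPa).
#' @param dims substrate box extents (um).
#' @param n_div elements per axis.
#' @param nu,eta substrate Poisson ratio and viscosity (Pa s).
#' @param mech a \code{mechanical_params}.
#' @param fate a \code{fate_params}.
#' @param initial_cells data.frame with columns x, y, z, phenotype; the
#'   default seeds one MSC at the origin corner.
#' @param n_steps number of time steps.
#' @param record_every record cadence in steps.
#' @param seed base RNG seed (replicate k uses seed + k - 1).
#' @param replicates number of replicate runs.
#' @param d_max per-step translocation cap (um).
#' @param max_cells hard population cap (run stops when exceeded).
#' @param stop_rule optional function(events, cells) -> logical; a TRUE
#'   ends the replicate early (after recording the step).
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(E,
                              dims = c(400, 200, 200),
                              n_div = c(40, 20, 20),
                              nu = 0.3, eta = 1000,
                              mech = mechanical_params(),
                              fate = fate_params(),
                              initial_cells = NULL,
                              n_steps = 252L,
                              record_every = 1L,
                              seed = 1L,
                              replicates = 20L,
                              d_max = 0.5 * mech$r_cell,
                              max_cells = 64L,
                              stop_rule = NULL) {
  mat <- material_props(E, nu, eta)
  if (is.null(initial_cells)) {
    r <- mech$r_cell
    initial_cells <- data.frame(x = r, y = r, z = r, phenotype = "MSC",
                                stringsAsFactors = FALSE)
  }
  if (any(!initial_cells$phenotype %in% PHENOTYPES)) {
    stop("invalid config: unknown phenotype in initial_cells", call. = FALSE)
  }
  r <- mech$r_cell
  ok <- initial_cells$x >= r & initial_cells$x <= dims[1] - r &
    initial_cells$y >= r & initial_cells$y <= dims[2] - r &
    initial_cells$z >= r & initial_cells$z <= dims[3] - r
  if (!all(ok)) {
    stop("invalid config: initial cells must sit at least one radius inside the box",
         call. = FALSE)
  }
  structure(list(dims = dims, n_div = n_div, mat = mat, mech = mech,
                 fate = fate, initial_cells = initial_cells,
                 n_steps = as.integer(n_steps),
                 record_every = as.integer(record_every),
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 d_max = d_max, max_cells = as.integer(max_cells),
                 stop_rule = stop_rule),
            class = "simulation_config")
}

#' Scenario presets
#'
#' The six stiffness scenarios: soft (0.1, 1 kPa, neurogenic tissue),
#' intermediate (20, 25 kPa, chondrogenic) and hard (30, 45 kPa,
#' osteogenic). Presets differ only in E; everything else keeps the
#' reference defaults (overridable through \code{...}).
#'
#' @param E one of 0.1, 1, 20, 25, 30, 45 (other moduli are allowed but
#'   are not presets).
#' @param ... overrides passed to \code{simulation_config}.
#' @return a \code{simulation_config}.
#' @export
scenario_config <- function(E, ...) {
  simulation_config(E = E, ...)
}

#' @rdname scenario_config
#' @export
scenario_stiffnesses <- function() c(0.1, 1, 20, 25, 30, 45)

new_population <- function(cfg) {
  cells <- vector("list", nrow(cfg$initial_cells))
  for (i in seq_along(cells)) {
    cells[[i]] <- cell_state(i, as.numeric(cfg$initial_cells[i, c("x", "y", "z")]),
                             cfg$initial_cells$phenotype[i], cfg$mech)
  }
  list(cells = cells, time_h = 0, next_id = length(cells) + 1L)
}

event_row <- function(time_h, id, kind, gamma, before, after) {
  data.frame(time_h = time_h, time_days = time_h / 24, cell_id = id,
             kind = kind, gamma = gamma, phenotype_before = before,
             phenotype_after = after, stringsAsFactors = FALSE)
}

#' Advance the population by one time step
#'
#' Per cell, in fixed id order: mechano-sensing, traction, random
#' protrusion, force balance (polarisation, velocity, translocation),
#' mechanical signal, maturation accrual, fate decision. Then proposed
#' moves are applied under the minimum-separation and box constraints,
#' fate events (apoptoses, differentiations, proliferations) are
#' executed, contacts are re-detected and time advances by tau.
#'
#' @param state population state from \code{new_population} or a prior step.
#' @param op an \code{fe_operator} for the scenario.
#' @param cfg a \code{simulation_config}.
#' @return list with \code{state}, \code{records} (one row per cell) and
#'   \code{events} (zero or more rows).
#' @export
sim_step <- function(state, op, cfg) {
  p <- cfg$mech
  fp <- cfg$fate
  cells <- state$cells
  nc <- length(cells)
  moves <- matrix(0, nc, 3L)
  decisions <- vector("list", nc)
  events <- list()
  t_next_h <- state$time_h + p$tau

  for (i in seq_len(nc)) {
    cl <- cells[[i]]
    cl <- mechanosense(cl, op, p, fp)
    trac <- traction_forces(cl, p, cl$e_pol, fp)
    prot <- protrusion_force(trac$net)
    fb <- resolve_motion(trac$net, prot, p, cfg$mat, cl$e_pol)
    e_pol <- fb$e_pol
    if (is.null(e_pol)) e_pol <- c(1, 0, 0)
    cl$e_pol <- e_pol
    cl$F_trac_net <- trac$net
    gam <- mechanical_signal(cl$node_tensor, e_pol)
    cl$gamma <- gam
    had_MI1 <- cl$MI >= 1
    cl$MI <- update_MI(cl$MI, gam, p$tau, fp)
    if (!had_MI1 && cl$MI >= 1) {
      events[[length(events) + 1L]] <-
        event_row(t_next_h, cl$id, "matured", gam, cl$phenotype, cl$phenotype)
    }
    cl$age_in_phenotype <- cl$age_in_phenotype + p$tau
    decisions[[i]] <- decide_fate(cl, gam, fp)
    # step-limited translocation
    dlen <- sqrt(sum(fb$d^2))
    d <- if (dlen > cfg$d_max) fb$d * (cfg$d_max / dlen) else fb$d
    cl$v <- sqrt(sum(d^2)) / p$tau
    moves[i, ] <- d
    cells[[i]] <- cl
  }

  pos0 <- t(vapply(cells, function(cl) cl$centroid, numeric(3)))
  sep <- enforce_separation(pos0, moves, p$r_cell, cfg$dims)
  for (i in seq_len(nc)) cells[[i]]$centroid <- sep$positions[i, ]

  # records reflect the completed motion of this step, before fate events
  records <- data.frame(
    time_h = t_next_h, time_days = t_next_h / 24,
    cell_id = vapply(cells, function(cl) cl$id, integer(1)),
    phenotype = vapply(cells, function(cl) cl$phenotype, character(1)),
    x = sep$positions[, 1], y = sep$positions[, 2], z = sep$positions[, 3],
    MI = vapply(cells, function(cl) cl$MI, numeric(1)),
    gamma = vapply(cells, function(cl) cl$gamma, numeric(1)),
    F_trac = vapply(cells, function(cl) sqrt(sum(cl$F_trac_net^2)), numeric(1)),
    v = vapply(cells, function(cl) cl$v, numeric(1)),
    event = "", stringsAsFactors = FALSE
  )

  # apply fate events in id order
  keep <- rep(TRUE, nc)
  newborns <- list()
  next_id <- state$next_id
  for (i in seq_len(nc)) {
    cl <- cells[[i]]
    dec <- decisions[[i]]
    if (dec$apoptosis) {
      keep[i] <- FALSE
      records$event[i] <- "apoptosis"
      events[[length(events) + 1L]] <-
        event_row(t_next_h, cl$id, "apoptosis", cl$gamma, cl$phenotype, NA)
      next
    }
    target <- dec$differentiate
    if (dec$proliferate) {
      phen <- if (!is.na(target)) target else cl$phenotype
      alive_cells <- c(cells[keep], newborns)
      daughters <- apply_proliferation(cl, alive_cells, p, cfg$dims,
                                       phenotype = phen)
      if (is.null(daughters)) {
        records$event[i] <- "proliferation_deferred"
        events[[length(events) + 1L]] <-
          event_row(t_next_h, cl$id, "proliferation_deferred", cl$gamma,
                    cl$phenotype, cl$phenotype)
        if (!is.na(target)) {
          # still differentiate even if the division had to be deferred
          events[[length(events) + 1L]] <-
            event_row(t_next_h, cl$id, "differentiation", cl$gamma,
                      cl$phenotype, target)
          cl$phenotype <- target
          cl$MI <- 0
          cl$age_in_phenotype <- 0
          cells[[i]] <- cl
        }
        next
      }
      if (!is.na(target)) {
        events[[length(events) + 1L]] <-
          event_row(t_next_h, cl$id, "differentiation", cl$gamma,
                    cl$phenotype, target)
      }
      events[[length(events) + 1L]] <-
        event_row(t_next_h, cl$id, "proliferation", cl$gamma,
                  cl$phenotype, phen)
      records$event[i] <- paste0(if (!is.na(target)) "differentiation+" else "",
                                 "proliferation")
      d1 <- daughters[[1]]; d2 <- daughters[[2]]
      d1$id <- cl$id          # daughter 1 continues the mother's trajectory
      d2$id <- next_id
      next_id <- next_id + 1L
      cells[[i]] <- d1
      newborns[[length(newborns) + 1L]] <- d2
    } else if (!is.na(target)) {
      events[[length(events) + 1L]] <-
        event_row(t_next_h, cl$id, "differentiation", cl$gamma,
                  cl$phenotype, target)
      records$event[i] <- "differentiation"
      cl$phenotype <- target
      cl$MI <- 0
      cl$age_in_phenotype <- 0
      cells[[i]] <- cl
    }
  }
  cells <- c(cells[keep], newborns)
  cells <- detect_contacts(cells, p)

  list(state = list(cells = cells, time_h = t_next_h, next_id = next_id),
       records = records,
       events = if (length(events)) do.call(rbind, events) else empty_events())
}

empty_events <- function() {
  data.frame(time_h = numeric(0), time_days = numeric(0),
             cell_id = integer(0), kind = character(0), gamma = numeric(0),
             phenotype_before = character(0), phenotype_after = character(0),
             stringsAsFactors = FALSE)
}

#' Run one replicate
#'
#' Seeds the RNG, builds (or reuses) the substrate operator and advances
#' the population for \code{cfg$n_steps} steps or until the stop rule
#' fires or the population cap is exceeded.
#'
#' @param cfg a \code{simulation_config}.
#' @param seed RNG seed for this replicate.
#' @param op optional prebuilt \code{fe_operator} (the factorization is
#'   reused across replicates of a scenario).
#' @return list with \code{records}, \code{events}, \code{state},
#'   \code{seed}, \code{steps_run}.
#' @export
run_replicate <- function(cfg, seed = cfg$seed, op = NULL) {
  if (is.null(op)) {
    mesh <- build_hex_mesh(cfg$dims, cfg$n_div)
    op <- assemble_operator(mesh, cfg$mat)
  }
  set.seed(seed)
  state <- new_population(cfg)
  rec <- vector("list", cfg$n_steps)
  ev <- list(empty_events())
  steps <- 0L
  stop_next <- FALSE
  for (s in seq_len(cfg$n_steps)) {
    out <- sim_step(state, op, cfg)
    state <- out$state
    steps <- s
    if (s %% cfg$record_every == 0L) rec[[s]] <- out$records
    if (nrow(out$events)) ev[[length(ev) + 1L]] <- out$events
    if (stop_next) break
    if (length(state$cells) == 0L) break
    if (length(state$cells) > cfg$max_cells) break
    if (!is.null(cfg$stop_rule)) {
      events_so_far <- do.call(rbind, ev)
      # run one further step after the rule fires, so the effect of the
      # stopping event is present in the records
      if (isTRUE(cfg$stop_rule(events_so_far, state$cells))) stop_next <- TRUE
    }
  }
  list(records = do.call(rbind, rec[!vapply(rec, is.null, logical(1))]),
       events = do.call(rbind, ev), state = state, seed = seed,
       steps_run = steps)
}

#' First event time across a replicate's event log
#'
#' @param events event log data.frame.
#' @param kind event kind.
#' @param phenotype optional phenotype filter.
#' @param phenotype_col column to match the filter against.
#' @return time in days of the earliest matching event, or NA.
#' @export
first_event_time <- function(events, kind, phenotype = NULL,
                             phenotype_col = "phenotype_after") {
  sel <- events$kind == kind
  if (!is.null(phenotype)) sel <- sel & events[[phenotype_col]] %in% phenotype
  if (!any(sel)) return(NA_real_)
  min(events$time_days[sel])
}

#' Stop rule helpers
#'
#' \code{stop_after_event(kind, phenotype)} builds a stop rule that ends
#' a replicate once an event of the given kind (and, optionally,
#' resulting phenotype) has been logged.
#'
#' @param kind event kind (e.g. "differentiation", "proliferation",
#'   "matured").
#' @param phenotype optional phenotype filter (matched against the
#'   post-event phenotype).
#' @return function(events, cells) -> logical.
#' @export
stop_after_event <- function(kind, phenotype = NULL) {
  function(events, cells) {
    !is.na(first_event_time(events, kind, phenotype))
  }
}

#' Run a scenario with replicates
#'
#' Factorizes the substrate operator once, runs \code{cfg$replicates}
#' independently seeded replicates (seed, seed + 1, ...), and summarises
#' event timings and final phenotype composition across replicates.
#'
#' @param cfg a \code{simulation_config}.
#' @param op optional prebuilt operator.
#' @param keep_records keep per-step records of each replicate.
#' @return object of class \code{scenario_result}: list with
#'   \code{replicates} (per-replicate results), \code{summary}
#'   (data.frame of cross-replicate means and sds) and \code{cfg}.
#' @export
run_scenario <- function(cfg, op = NULL, keep_records = TRUE) {
  if (is.null(op)) {
    mesh <- build_hex_mesh(cfg$dims, cfg$n_div)
    op <- assemble_operator(mesh, cfg$mat)
  }
  reps <- vector("list", cfg$replicates)
  for (k in seq_len(cfg$replicates)) {
    res <- run_replicate(cfg, seed = cfg$seed + k - 1L, op = op)
    if (!keep_records) res$records <- NULL
    reps[[k]] <- res
  }
  list(replicates = reps, summary = summarize_replicates(reps), cfg = cfg) |>
    structure(class = "scenario_result")
}

# Cross-replicate summary of the quantities of interest.
summarize_replicates <- function(reps) {
  metric <- function(fn) vapply(reps, fn, numeric(1))
  m <- list(
    t_first_matured = metric(function(r)
      first_event_time(r$events, "matured", "MSC")),
    t_first_differentiation = metric(function(r)
      first_event_time(r$events, "differentiation")),
    t_first_proliferation = metric(function(r)
      first_event_time(r$events, "proliferation"))
  )
  for (ph in c("osteoblast", "chondrocyte", "neuroblast")) {
    m[[paste0("t_first_diff_", ph)]] <- metric(function(r)
      first_event_time(r$events, "differentiation", ph))
    m[[paste0("t_first_prolif_", ph)]] <- metric(function(r)
      first_event_time(r$events, "proliferation", ph,
                       phenotype_col = "phenotype_before"))
    m[[paste0("t_first_matured_", ph)]] <- metric(function(r)
      first_event_time(r$events, "matured", ph))
  }
  data.frame(
    metric = names(m),
    mean = vapply(m, function(x) if (all(is.na(x))) NA_real_
                  else mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(m, function(x) if (sum(!is.na(x)) < 2L) NA_real_
                else stats::sd(x, na.rm = TRUE), numeric(1)),
    n = vapply(m, function(x) sum(!is.na(x)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario E = %g kPa, %d replicates\n", x$cfg$mat$E,
              length(x$replicates)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Modal phenotype of the first differentiation across replicates
#'
#' @param result a \code{scenario_result}.
#' @return the most frequent first-differentiation phenotype, or NA when
#'   no replicate differentiates.
#' @export
modal_first_differentiation <- function(result) {
  ph <- vapply(result$replicates, function(r) {
    ev <- r$events[r$events$kind == "differentiation", , drop = FALSE]
    if (!nrow(ev)) NA_character_ else ev$phenotype_after[which.min(ev$time_days)]
  }, character(1))
  ph <- ph[!is.na(ph)]
  if (!length(ph)) return(NA_character_)
  names(sort(table(ph), decreasing = TRUE))[1]
}
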