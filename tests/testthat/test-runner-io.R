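# Small driver fixture: soft box at the reference element size.
driver_cfg <- function(E = 45, n_steps = 6L, seed = 21L, ...) {
  scenario_config(E, dims = c(120, 80, 80), n_div = c(12, 8, 8),
                  n_steps = n_steps, replicates = 1L, seed = seed, ...)
}

test_that("a replicate is bitwise reproducible under the same seed", {
  cfg <- driver_cfg(n_steps = 10L)
  op <- assemble_operator(build_hex_mesh(cfg$dims, cfg$n_div), cfg$mat)
  r1 <- run_replicate(cfg, seed = 33, op = op)
  r2 <- run_replicate(cfg, seed = 33, op = op)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$events, r2$events)
  r3 <- run_replicate(cfg, seed = 34, op = op)
  expect_false(identical(r1$records$x, r3$records$x))
})

test_that("one step of one replicate writes exactly one record row", {
  cfg <- driver_cfg(n_steps = 1L)
  r <- run_replicate(cfg)
  expect_equal(nrow(r$records), 1L)
  expect_equal(r$records$time_h, cfg$mech$tau)
  expect_named(r$records,
               c("time_h", "time_days", "cell_id", "phenotype", "x", "y", "z",
                 "MI", "gamma", "F_trac", "v", "event"))
})

test_that("an over-threshold signal removes the cell by apoptosis", {
  # soft substrate gives a large signal; lowering the apoptosis threshold
  # (keeping the band order valid) must kill the cell and empty the run
  fp <- fate_params(gamma_s = 0.01, gamma_c = 0.02, gamma_u = 0.03,
                    gamma_apop = 0.05,
                    gamma_prof = c(MSC = 0.02, osteoblast = 0.02,
                                   chondrocyte = 0.02, neuroblast = 0.02))
  cfg <- driver_cfg(E = 0.1, n_steps = 5L, fate = fp)
  r <- run_replicate(cfg)
  expect_true("apoptosis" %in% r$events$kind)
  expect_equal(length(r$state$cells), 0L)
  expect_lt(r$steps_run, 5L)
})

test_that("a corner-seeded cell drifts into the box interior", {
  cfg <- driver_cfg(E = 45, n_steps = 20L)
  op <- assemble_operator(build_hex_mesh(cfg$dims, cfg$n_div), cfg$mat)
  start <- c(20, 20, 20)
  inward <- vapply(1:10, function(k) {
    r <- run_replicate(cfg, seed = 100 + k, op = op)
    last <- r$records[nrow(r$records), c("x", "y", "z")]
    sqrt(sum((as.numeric(last) - start)^2)) > 10 &&
      all(as.numeric(last) >= start - 1e-9)
  }, logical(1))
  expect_gte(mean(inward), 0.9)
})

test_that("translocation length obeys the drag bound and the step cap", {
  cfg <- driver_cfg(n_steps = 8L)
  r <- run_replicate(cfg, seed = 3)
  p <- cfg$mech
  coef <- 6 * pi * p$r_cell * cfg$mat$eta * 1e-3 / 3600
  step_len <- r$records$v * p$tau
  bound <- r$records$F_trac * 2 * p$tau / coef  # |F_drag| <= 2 |F_trac|
  expect_true(all(step_len <= pmin(bound, cfg$d_max) + 1e-9))
})

test_that("population separation holds after every recorded step", {
  # force frequent divisions: start two cells close together
  init <- data.frame(x = c(40, 80), y = c(40, 40), z = c(40, 40),
                     phenotype = "MSC")
  cfg <- driver_cfg(E = 45, n_steps = 30L, initial_cells = init)
  r <- run_replicate(cfg, seed = 8)
  for (t in unique(r$records$time_h)) {
    pos <- as.matrix(r$records[r$records$time_h == t, c("x", "y", "z")])
    if (nrow(pos) >= 2) {
      expect_gte(min(dist(pos)), 2 * cfg$mech$r_cell - 1e-9)
    }
    expect_true(all(pos >= cfg$mech$r_cell - 1e-9))
    expect_true(all(sweep(pos, 2, cfg$dims) <= -cfg$mech$r_cell + 1e-9))
  }
  # population count never shrinks in this division-only run
  times <- sort(unique(r$records$time_h))
  counts <- vapply(times, function(t) sum(r$records$time_h == t), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("scenario summaries equal brute-force recomputation from the logs", {
  cfg <- driver_cfg(E = 45, n_steps = 28L)
  cfg$replicates <- 3L
  res <- run_scenario(cfg)
  s <- res$summary
  tdiff <- vapply(res$replicates, function(r) {
    ev <- r$events[r$events$kind == "differentiation", , drop = FALSE]
    if (nrow(ev)) min(ev$time_days) else NA_real_
  }, numeric(1))
  expect_equal(s$mean[s$metric == "t_first_differentiation"],
               mean(tdiff, na.rm = TRUE))
  expect_equal(s$n[s$metric == "t_first_differentiation"], sum(!is.na(tdiff)))
  expect_s3_class(res, "scenario_result")
})

test_that("traction summary reports the trace and flags injected jumps", {
  cfg <- driver_cfg(n_steps = 10L)
  r <- run_replicate(cfg, seed = 12)
  st <- summarize_traction(r$records, r$events)
  expect_equal(st$trace$mean_F_trac, r$records$F_trac)  # single cell

  # synthetic trace with one discontinuity
  fake <- data.frame(time_days = (1:40) / 4,
                     F_trac = c(rep(10, 20), rep(13, 20)) + sin(1:40) * 0.05)
  # event fires at day 5.0; its effect shows on the following step
  ev <- data.frame(time_h = 5 * 24, time_days = 5, cell_id = 1L,
                   kind = "proliferation", gamma = 0.01,
                   phenotype_before = "MSC", phenotype_after = "MSC")
  st2 <- summarize_traction(fake, ev)
  expect_true(st2$markers$jump_after[1])
  expect_equal(st2$markers$direction[1], "increase")
  expect_lte(sum(st2$trace$jump), 2)
  expect_error(summarize_traction(fake[0, ]), "empty input")
})

test_that("CSV, VTK and JSON writers produce well-formed files", {
  cfg <- driver_cfg(n_steps = 3L)
  r <- run_replicate(cfg, seed = 2)
  td <- withr::local_tempdir()

  csv <- file.path(td, "steps.csv")
  write_step_csv(r$records, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(r$records))
  expect_equal(back$gamma, r$records$gamma, tolerance = 1e-12)

  write_events_csv(r$events, file.path(td, "events.csv"))
  expect_true(file.exists(file.path(td, "events.csv")))

  mesh <- build_hex_mesh(c(20, 20, 20), c(2, 2, 2))
  vtk <- file.path(td, "mesh.vtk")
  write_vtk_mesh(mesh, vtk, displacement = matrix(0, mesh$n_nodes, 3))
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_equal(lines[5], sprintf("POINTS %d double", mesh$n_nodes))
  expect_true(any(grepl("^CELL_TYPES 8$", lines)))
  expect_true(any(grepl("VECTORS displacement double", lines)))

  vtk2 <- file.path(td, "cells.vtk")
  write_vtk_cells(r$state$cells, vtk2)
  expect_true(any(grepl("SCALARS phenotype int", readLines(vtk2))))

  cfg$replicates <- 2L
  res <- run_scenario(cfg)
  js <- file.path(td, "summary.json")
  write_summary_json(res, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$E_kPa, 45)
  expect_equal(parsed$replicates, 2L)
})

test_that("YAML configs round-trip into a valid configuration", {
  td <- withr::local_tempdir()
  path <- file.path(td, "run.yaml")
  writeLines(c("schema_version: 1", "E: 30", "nu: 0.3", "eta: 1000",
               "dims: [200, 100, 100]", "n_div: [20, 10, 10]",
               "r_cell: 20", "tau: 6", "t_min: 4", "t_p: 200",
               "n_steps: 12", "seed: 5", "replicates: 2"), path)
  cfg <- read_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$mat$E, 30)
  expect_equal(cfg$n_div, c(20, 10, 10))
  expect_equal(cfg$n_steps, 12L)

  writeLines(c("E: 30", "bogus_key: 1"), path)
  expect_error(read_config(path), "unknown keys")
})

test_that("invalid configurations fail before any computation", {
  expect_error(simulation_config(E = -1), "invalid config")
  expect_error(simulation_config(E = 10, nu = 0.7), "invalid config")
  expect_error(simulation_config(E = 10,
                                 initial_cells = data.frame(x = 5, y = 50, z = 50,
                                                            phenotype = "MSC")),
               "invalid config")
  expect_error(fate_params(gamma_l = 0.5, gamma_s = 0.04), "invalid config")
  expect_error(mechanical_params(sigma_max = 10), "invalid config")
})
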