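#' Write per-step cell records as CSV
#'
#' One row per cell per recorded step: time (h and days), cell id,
#' phenotype, centroid (um), maturation index, mechanical signal gamma,
#' net traction magnitude (nN), realized speed (um/h) and event flag.
#'
#' @param records records data.frame from \code{run_replicate}.
#' @param path output file.
#' @export
write_step_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write the event log as CSV
#' @param events events data.frame from \code{run_replicate}.
#' @param path output file.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write the substrate mesh (and optionally a displacement field) as a
#' legacy-ASCII VTK unstructured grid
#'
#' Hexahedra use VTK cell type 12 with the package's node ordering,
#' which already follows the VTK convention.
#'
#' @param mesh a \code{substrate_mesh}.
#' @param path output file (.vtk).
#' @param displacement optional n_nodes x 3 field written as point-data
#'   vectors.
#' @export
write_vtk_mesh <- function(mesh, path, displacement = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mechanofate substrate", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", mesh$n_nodes)), con)
  utils::write.table(format(mesh$node_coords, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", mesh$n_elem, mesh$n_elem * 9L), con)
  utils::write.table(cbind(8L, mesh$hex - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", mesh$n_elem), con)
  writeLines(as.character(rep(12L, mesh$n_elem)), con)
  if (!is.null(displacement)) {
    writeLines(c(sprintf("POINT_DATA %d", mesh$n_nodes),
                 "VECTORS displacement double"), con)
    utils::write.table(displacement, con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a population snapshot as a VTK point cloud
#'
#' Cell centroids with phenotype code (1 MSC, 2 osteoblast,
#' 3 chondrocyte, 4 neuroblast), maturation index and mechanical signal
#' as point scalars.
#'
#' @param cells list of \code{cell_state}.
#' @param path output file (.vtk).
#' @export
write_vtk_cells <- function(cells, path) {
  n <- length(cells)
  pos <- t(vapply(cells, function(cl) cl$centroid, numeric(3)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mechanofate cells", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(pos, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", n, 2L * n), con)
  utils::write.table(cbind(1L, seq_len(n) - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", n), con)
  writeLines(as.character(rep(1L, n)), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS phenotype int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(vapply(cells, function(cl) cl$phenotype,
                                       character(1)), PHENOTYPES)), con)
  writeLines(c("SCALARS MI double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(vapply(cells, function(cl) cl$MI, numeric(1))), con)
  writeLines(c("SCALARS gamma double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(vapply(cells, function(cl) cl$gamma, numeric(1))), con)
  invisible(path)
}

#' Write a cross-replicate scenario summary as JSON
#'
#' @param result a \code{scenario_result}.
#' @param path output file (.json).
#' @export
write_summary_json <- function(result, path) {
  s <- result$summary
  out <- list(
    E_kPa = result$cfg$mat$E,
    replicates = length(result$replicates),
    metrics = stats::setNames(
      lapply(seq_len(nrow(s)), function(i)
        list(mean_days = s$mean[i], sd_days = s$sd[i], n = s$n[i])),
      s$metric)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value schema (version 1). Recognised keys: \code{E},
#' \code{dims}, \code{n_div}, \code{nu}, \code{eta}, \code{n_steps},
#' \code{record_every}, \code{seed}, \code{replicates}, \code{d_max},
#' plus any field of \code{mechanical_params} (e.g. \code{K_pas},
#' \code{sigma_max}, \code{r_cell}, \code{tau}) or \code{fate_params}
#' (e.g. \code{t_min}, \code{gamma_l}). Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a \code{simulation_config}.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$schema_version) && y$schema_version != 1) {
    stop("invalid config: unsupported schema_version", call. = FALSE)
  }
  y$schema_version <- NULL
  mech_keys <- names(formals(mechanical_params))
  fate_keys <- setdiff(names(formals(fate_params)), "concurrent")
  cfg_keys <- c("E", "dims", "n_div", "nu", "eta", "n_steps", "record_every",
                "seed", "replicates", "d_max", "max_cells", "concurrent")
  unknown <- setdiff(names(y), c(mech_keys, fate_keys, cfg_keys))
  if (length(unknown)) {
    stop("invalid config: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  mech <- do.call(mechanical_params, y[intersect(names(y), mech_keys)])
  fargs <- y[intersect(names(y), fate_keys)]
  if (!is.null(y$concurrent)) fargs$concurrent <- y$concurrent
  fate <- do.call(fate_params, fargs)
  cargs <- y[intersect(names(y), setdiff(cfg_keys, "concurrent"))]
  cargs$mech <- mech
  cargs$fate <- fate
  do.call(simulation_config, cargs)
}
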