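#' Centroid-to-centroid vector between two cells
#'
#' @param ci,cj \code{cell_state} objects (distinct).
#' @return vector from cell i to cell j (um).
#' @export
centroid_vector <- function(ci, cj) {
  if (ci$id == cj$id) stop("centroid_vector needs two distinct cells", call. = FALSE)
  cj$centroid - ci$centroid
}

#' Detect cell-cell contacts and suppress common membrane nodes
#'
#' For every pair of cells closer than \code{2 r + delta_c}, the
#' membrane nodes of each cell that lie within \code{r + delta_c} of the
#' other cell's centroid are marked inactive ("common nodes"): they
#' exert no sensing force while the contact lasts, though they still
#' carry traction. With the default 24-node template and
#' \code{delta_c = 0.25 r}, two cells at exact contact share between 1
#' and 4 common nodes per cell, and nodes reactivate automatically when
#' the pair separates.
#'
#' @param cells list of \code{cell_state}.
#' @param p a \code{mechanical_params}.
#' @param delta_c contact tolerance (um); default \code{0.25 * r_cell}.
#' @return the list of cells with updated \code{node_active} flags.
#' @export
detect_contacts <- function(cells, p, delta_c = 0.25 * p$r_cell) {
  r <- p$r_cell
  nc <- length(cells)
  active <- lapply(cells, function(cl) rep(TRUE, nrow(cl$membrane_dirs)))
  if (nc >= 2L) {
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        xij <- cells[[j]]$centroid - cells[[i]]$centroid
        if (sqrt(sum(xij^2)) <= 2 * r + delta_c) {
          pi_ <- membrane_points(cells[[i]], p)
          pj_ <- membrane_points(cells[[j]], p)
          di <- sqrt(rowSums(sweep(pi_, 2L, cells[[j]]$centroid)^2))
          dj <- sqrt(rowSums(sweep(pj_, 2L, cells[[i]]$centroid)^2))
          active[[i]][di <= r + delta_c] <- FALSE
          active[[j]][dj <= r + delta_c] <- FALSE
        }
      }
    }
  }
  for (i in seq_len(nc)) cells[[i]]$node_active <- active[[i]]
  cells
}

#' Enforce minimum separation and box confinement
#'
#' Applies proposed translocations, then resolves violations of the
#' non-interference constraint (centroid distance at least one cell
#' diameter) by pushing each violating pair apart symmetrically along
#' their centroid line, sweeping over pairs in cell-id order up to
#' \code{max_sweeps} times; centroids are clamped to stay at least one
#' radius inside every box face.
#'
#' @param positions n x 3 matrix of current centroids (um).
#' @param moves n x 3 matrix of proposed translocations (um).
#' @param r cell radius (um).
#' @param box box extents (um).
#' @param max_sweeps sweep limit.
#' @return list with \code{positions} (corrected n x 3 matrix) and
#'   \code{resolved} (FALSE if the packing could not be resolved, in
#'   which case the pre-move positions are returned frozen).
#' @export
enforce_separation <- function(positions, moves, r, box, max_sweeps = 60L) {
  positions <- matrix(positions, ncol = 3)
  old <- positions
  pos <- positions + matrix(moves, ncol = 3)
  n <- nrow(pos)
  clamp <- function(q) {
    for (d in 1:3) q[, d] <- pmin(pmax(q[, d], r), box[d] - r)
    q
  }
  pos <- clamp(pos)
  if (n >= 2L) {
    ok <- FALSE
    for (sweep_i in seq_len(max_sweeps)) {
      moved <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          xij <- pos[j, ] - pos[i, ]
          dist <- sqrt(sum(xij^2))
          if (dist < 2 * r - 1e-12) {
            dir <- if (dist > 1e-12) xij / dist else c(1, 0, 0)
            push <- (2 * r - dist) / 2
            pos[i, ] <- pos[i, ] - push * dir
            pos[j, ] <- pos[j, ] + push * dir
            moved <- TRUE
          }
        }
      }
      pos <- clamp(pos)
      if (!moved) { ok <- TRUE; break }
    }
    # after clamping, re-check: if still violating, freeze the step
    dmin <- Inf
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      dmin <- min(dmin, sqrt(sum((pos[j, ] - pos[i, ])^2)))
    }
    if (!ok && dmin < 2 * r - 1e-9) {
      return(list(positions = clamp(old), resolved = FALSE))
    }
  }
  list(positions = pos, resolved = TRUE)
}
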