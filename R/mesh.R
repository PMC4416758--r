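#' Build a regular hexahedral substrate mesh
#'
#' Discretises an axis-aligned box into a structured grid of 8-node
#' (trilinear) hexahedra. Node numbering runs fastest along x, then y,
#' then z, starting at 1 in the corner at the origin; element connectivity
#' follows the VTK hexahedron convention (bottom face counter-clockwise,
#' then top face). The origin sits at the box corner where the initial
#' cell is seeded, so all coordinates are non-negative.
#'
#' @param dims numeric length-3, box extents in micrometres.
#' @param n_div integer length-3, number of elements per axis.
#' @return An object of class \code{substrate_mesh}: list with
#'   \code{node_coords} (n_nodes x 3, um), \code{hex} (n_elem x 8 node
#'   indices), \code{dims}, \code{n_div}, \code{h} (element edge lengths),
#'   \code{n_nodes}, \code{n_elem}.
#' @examples
#' m <- build_hex_mesh(c(400, 200, 200), c(40, 20, 20))
#' m$n_elem   # 16000
#' m$n_nodes  # 18081
#' @export
build_hex_mesh <- function(dims, n_div) {
  dims <- as.numeric(dims)
  n_div <- as.integer(n_div)
  if (length(dims) != 3L || length(n_div) != 3L) {
    stop("dims and n_div must each have length 3", call. = FALSE)
  }
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("invalid config: box extents must be positive", call. = FALSE)
  }
  if (any(is.na(n_div)) || any(n_div < 1L)) {
    stop("invalid config: division counts must be positive integers", call. = FALSE)
  }
  nx <- n_div[1]; ny <- n_div[2]; nz <- n_div[3]
  h <- dims / n_div
  xs <- seq(0, dims[1], length.out = nx + 1L)
  ys <- seq(0, dims[2], length.out = ny + 1L)
  zs <- seq(0, dims[3], length.out = nz + 1L)
  node_coords <- cbind(
    x = rep(xs, times = (ny + 1L) * (nz + 1L)),
    y = rep(rep(ys, each = nx + 1L), times = nz + 1L),
    z = rep(zs, each = (nx + 1L) * (ny + 1L))
  )
  # node index for grid position (ix, iy, iz), all 0-based
  nid <- function(ix, iy, iz) 1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)
  ex <- rep(0L:(nx - 1L), times = ny * nz)
  ey <- rep(rep(0L:(ny - 1L), each = nx), times = nz)
  ez <- rep(0L:(nz - 1L), each = nx * ny)
  hex <- cbind(
    nid(ex,      ey,      ez),
    nid(ex + 1L, ey,      ez),
    nid(ex + 1L, ey + 1L, ez),
    nid(ex,      ey + 1L, ez),
    nid(ex,      ey,      ez + 1L),
    nid(ex + 1L, ey,      ez + 1L),
    nid(ex + 1L, ey + 1L, ez + 1L),
    nid(ex,      ey + 1L, ez + 1L)
  )
  structure(
    list(node_coords = node_coords, hex = hex, dims = dims, n_div = n_div,
         h = h, n_nodes = nrow(node_coords), n_elem = nrow(hex)),
    class = "substrate_mesh"
  )
}

#' @export
print.substrate_mesh <- function(x, ...) {
  cat(sprintf("substrate_mesh: %g x %g x %g um, %d x %d x %d elements (%d hexahedra, %d nodes)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$n_div[1], x$n_div[2], x$n_div[3], x$n_elem, x$n_nodes))
  invisible(x)
}

# Local node coordinates of the reference hexahedron ([-1,1]^3, VTK order).
hex8_local <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1
), ncol = 3, byrow = TRUE)

# Trilinear shape functions at local coords xi (m x 3) -> m x 8.
hex8_shape <- function(xi) {
  xi <- matrix(xi, ncol = 3)
  out <- matrix(0, nrow(xi), 8L)
  for (a in 1:8) {
    out[, a] <- (1 + xi[, 1] * hex8_local[a, 1]) *
      (1 + xi[, 2] * hex8_local[a, 2]) *
      (1 + xi[, 3] * hex8_local[a, 3]) / 8
  }
  out
}

# Shape-function gradients in local coords at a single local point: 8 x 3.
hex8_dshape <- function(xi) {
  g <- matrix(0, 8L, 3L)
  for (a in 1:8) {
    la <- hex8_local[a, ]
    g[a, 1] <- la[1] * (1 + xi[2] * la[2]) * (1 + xi[3] * la[3]) / 8
    g[a, 2] <- la[2] * (1 + xi[1] * la[1]) * (1 + xi[3] * la[3]) / 8
    g[a, 3] <- la[3] * (1 + xi[1] * la[1]) * (1 + xi[2] * la[2]) / 8
  }
  g
}

# Locate points in the structured grid. pts: m x 3 (um).
# Returns list(elem = element index, xi = m x 3 local coords in [-1,1]).
locate_points <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 3)
  eps <- 1e-9 * max(mesh$dims)
  inside <- pts[, 1] >= -eps & pts[, 1] <= mesh$dims[1] + eps &
    pts[, 2] >= -eps & pts[, 2] <= mesh$dims[2] + eps &
    pts[, 3] >= -eps & pts[, 3] <= mesh$dims[3] + eps
  if (!all(inside)) {
    stop(sprintf("out of domain: point (%.3g, %.3g, %.3g) lies outside the substrate box",
                 pts[which(!inside)[1], 1], pts[which(!inside)[1], 2],
                 pts[which(!inside)[1], 3]), call. = FALSE)
  }
  ixs <- matrix(0L, nrow(pts), 3L)
  xi <- matrix(0, nrow(pts), 3L)
  for (d in 1:3) {
    i <- pmin(pmax(floor(pts[, d] / mesh$h[d]), 0), mesh$n_div[d] - 1L)
    ixs[, d] <- as.integer(i)
    xi[, d] <- 2 * (pts[, d] - i * mesh$h[d]) / mesh$h[d] - 1
  }
  elem <- 1L + ixs[, 1] + mesh$n_div[1] * (ixs[, 2] + mesh$n_div[2] * ixs[, 3])
  list(elem = elem, xi = xi)
}

# Trilinear interpolation weights for points: list(nodes = m x 8 indices,
# w = m x 8 weights). Used both to spread point loads and to sample fields.
point_weights <- function(mesh, pts) {
  loc <- locate_points(mesh, pts)
  list(nodes = mesh$hex[loc$elem, , drop = FALSE],
       w = hex8_shape(loc$xi),
       loc = loc)
}

# Interpolate a nodal field (n_nodes x k) at points. Returns m x k.
interp_at_points <- function(mesh, field, pts, pw = NULL) {
  if (is.null(pw)) pw <- point_weights(mesh, pts)
  m <- nrow(pw$w)
  out <- matrix(0, m, ncol(field))
  for (a in 1:8) {
    out <- out + pw$w[, a] * field[pw$nodes[, a], , drop = FALSE]
  }
  out
}

#' Small-strain tensor of a displacement field at a point
#'
#' Evaluates the symmetric gradient of the trilinear displacement
#' interpolant of the element containing \code{p}, at the local
#' coordinates of \code{p}. Affine displacement fields are reproduced
#' exactly (patch-test property of trilinear hexahedra).
#'
#' @param mesh a \code{substrate_mesh}.
#' @param disp nodal displacement matrix (n_nodes x 3, um).
#' @param p position (length 3, um), inside the box.
#' @return symmetric 3 x 3 small-strain tensor (dimensionless).
#' @export
strain_at_point <- function(mesh, disp, p) {
  strain_at_points(mesh, disp, matrix(p, ncol = 3))[1, , ]
}

# Vectorised version: pts m x 3 -> array m x 3 x 3.
strain_at_points <- function(mesh, disp, pts, loc = NULL) {
  pts <- matrix(pts, ncol = 3)
  if (is.null(loc)) loc <- locate_points(mesh, pts)
  m <- nrow(pts)
  out <- array(0, c(m, 3L, 3L))
  scale <- 2 / mesh$h  # d(xi)/d(x) for the regular grid
  for (i in seq_len(m)) {
    dN <- hex8_dshape(loc$xi[i, ])            # 8 x 3, local
    dNdx <- sweep(dN, 2L, scale, `*`)         # 8 x 3, global
    gu <- t(disp[mesh$hex[loc$elem[i], ], , drop = FALSE]) %*% dNdx  # 3 x 3
    out[i, , ] <- (gu + t(gu)) / 2
  }
  out
}
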