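# Shared small fixtures. Meshes keep the reference 10 um element size,
# since the sensing near-field scale is pinned to it.

small_mesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_hex_mesh(c(120, 80, 80), c(12, 8, 8))
    m
  }
})

small_operator <- local({
  ops <- list()
  function(E = 45) {
    key <- as.character(E)
    if (is.null(ops[[key]])) {
      ops[[key]] <<- assemble_operator(small_mesh(), material_props(E))
    }
    ops[[key]]
  }
})

# Independent single-hexahedron stiffness oracle: 3x3x3 Gauss quadrature
# with finite-difference shape-function gradients; shares no code with
# the implementation beyond the node ordering convention.
oracle_hex_stiffness <- function(h, E, nu) {
  corners <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  # reorder to VTK convention
  vtk <- c(1, 2, 4, 3, 5, 6, 8, 7)
  corners <- corners[vtk, ]
  shape <- function(xi) {
    # xi in [0,1]^3
    apply(corners, 1, function(cn) {
      prod(ifelse(cn == 1, xi, 1 - xi))
    })
  }
  dshape <- function(xi) {
    d <- matrix(0, 8, 3)
    e <- 1e-6
    for (k in 1:3) {
      xp <- xi; xm <- xi
      xp[k] <- xi[k] + e; xm[k] <- xi[k] - e
      d[, k] <- (shape(xp) - shape(xm)) / (2 * e)
    }
    d
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- (c(-sqrt(3 / 5), 0, sqrt(3 / 5)) + 1) / 2
  gw <- c(5, 8, 5) / 9 / 2
  K <- matrix(0, 24, 24)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    dN <- dshape(c(gp[i], gp[j], gp[k]))
    dNdx <- sweep(dN, 2, h, `/`)
    B <- matrix(0, 6, 24)
    ax <- 3 * (1:8) - 2
    B[1, ax] <- dNdx[, 1]; B[2, ax + 1] <- dNdx[, 2]; B[3, ax + 2] <- dNdx[, 3]
    B[4, ax] <- dNdx[, 2]; B[4, ax + 1] <- dNdx[, 1]
    B[5, ax + 1] <- dNdx[, 3]; B[5, ax + 2] <- dNdx[, 2]
    B[6, ax] <- dNdx[, 3]; B[6, ax + 2] <- dNdx[, 1]
    K <- K + gw[i] * gw[j] * gw[k] * prod(h) * (t(B) %*% D %*% B)
  }
  K
}

# Consistent nodal forces for a uniform traction t (nN/um^2) on the
# x = 0 or x = Lx face of a structured mesh: tributary-weighted by the
# bilinear face partition (corner 1/4, edge 1/2, interior 1 of a face
# element's quarter-areas).
uniaxial_face_loads <- function(mesh, sigma) {
  nx <- mesh$n_div[1]; ny <- mesh$n_div[2]; nz <- mesh$n_div[3]
  hy <- mesh$h[2]; hz <- mesh$h[3]
  f <- matrix(0, mesh$n_nodes, 3)
  for (face_x in c(0, mesh$dims[1])) {
    sgn <- if (face_x == 0) -1 else 1
    on_face <- which(abs(mesh$node_coords[, 1] - face_x) < 1e-9)
    for (nid in on_face) {
      y <- mesh$node_coords[nid, 2]; z <- mesh$node_coords[nid, 3]
      wy <- if (y < 1e-9 || y > mesh$dims[2] - 1e-9) 0.5 else 1
      wz <- if (z < 1e-9 || z > mesh$dims[3] - 1e-9) 0.5 else 1
      f[nid, 1] <- sgn * sigma * hy * hz * wy * wz
    }
  }
  f
}

# Solve the FE system under an explicit nodal load matrix (bypasses the
# point-load spreading), for patch tests.
solve_nodal_loads <- function(op, f) {
  mechanofate:::solve_operator(op, as.vector(t(f)))
}
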