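#' Substrate material properties
#'
#' Linear-elastic isotropic substrate with a Stokes-drag viscosity.
#' Defaults other than \code{E} follow the reference parameter set
#' (Poisson ratio 0.3, minimum substrate viscosity 1000 Pa s).
#'
#' @param E Young's modulus (kPa).
#' @param nu Poisson ratio (dimensionless, in [0, 0.5)).
#' @param eta substrate viscosity (Pa s), used in the drag law.
#' @return object of class \code{material_props}.
#' @export
material_props <- function(E, nu = 0.3, eta = 1000) {
  if (!is.finite(E) || E <= 0) stop("invalid config: E must be > 0", call. = FALSE)
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) {
    stop("invalid config: nu must be in [0, 0.5)", call. = FALSE)
  }
  if (!is.finite(eta) || eta <= 0) stop("invalid config: eta must be > 0", call. = FALSE)
  structure(list(E = E, nu = nu, eta = eta), class = "material_props")
}

# Isotropic elasticity matrix (6x6, Voigt order xx, yy, zz, xy, yz, zx),
# engineering shear strains. Units: kPa.
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Element stiffness (24 x 24) of a regular box hex8 element with edge
# lengths h = c(hx, hy, hz), 2x2x2 Gauss quadrature. DOF order:
# (u1x, u1y, u1z, u2x, ...). Units: kPa * um = nN / um.
hex8_stiffness <- function(h, E, nu, n_gauss = 2L) {
  D <- elasticity_matrix(E, nu)
  if (n_gauss == 2L) {
    gp <- c(-1, 1) / sqrt(3); gw <- c(1, 1)
  } else if (n_gauss == 3L) {
    gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gw <- c(5, 8, 5) / 9
  } else stop("n_gauss must be 2 or 3")
  detJ <- prod(h) / 8
  scale <- 2 / h
  K <- matrix(0, 24, 24)
  for (i in seq_along(gp)) for (j in seq_along(gp)) for (k in seq_along(gp)) {
    dNdx <- sweep(hex8_dshape(c(gp[i], gp[j], gp[k])), 2L, scale, `*`)
    B <- matrix(0, 6, 24)
    ax <- 3 * (1:8) - 2
    B[1, ax]     <- dNdx[, 1]
    B[2, ax + 1] <- dNdx[, 2]
    B[3, ax + 2] <- dNdx[, 3]
    B[4, ax]     <- dNdx[, 2]; B[4, ax + 1] <- dNdx[, 1]
    B[5, ax + 1] <- dNdx[, 3]; B[5, ax + 2] <- dNdx[, 2]
    B[6, ax]     <- dNdx[, 3]; B[6, ax + 2] <- dNdx[, 1]
    K <- K + gw[i] * gw[j] * gw[k] * detJ * (t(B) %*% D %*% B)
  }
  K
}

# Global stiffness assembly. All elements of the regular grid share one
# element matrix, so assembly is a replicated triplet pattern.
assemble_stiffness <- function(mesh, mat) {
  Ke <- hex8_stiffness(mesh$h, mat$E, mat$nu)
  nel <- mesh$n_elem
  edof <- matrix(0L, nel, 24L)
  for (a in 1:8) {
    edof[, 3 * a - 2L] <- 3L * mesh$hex[, a] - 2L
    edof[, 3 * a - 1L] <- 3L * mesh$hex[, a] - 1L
    edof[, 3 * a]      <- 3L * mesh$hex[, a]
  }
  ii <- edof[, rep(1:24, times = 24)]
  jj <- edof[, rep(1:24, each = 24)]
  xx <- rep(as.vector(Ke), each = nel)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = xx,
                            dims = c(3L * mesh$n_nodes, 3L * mesh$n_nodes))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# DOF indices suppressed by the 3-2-1 rule on three corner nodes of the
# z = 0 face: all three translations at the origin corner, the two
# off-axis translations at the corner along +x, and the z translation at
# the corner along +y. Removes exactly the six rigid-body modes of the
# otherwise free-floating substrate.
corner_constraints <- function(mesh) {
  nx <- mesh$n_div[1]; ny <- mesh$n_div[2]
  n1 <- 1L                          # (0, 0, 0)
  n2 <- nx + 1L                     # (Lx, 0, 0)
  n3 <- (nx + 1L) * ny + 1L         # (0, Ly, 0)
  sort(c(3L * n1 - 2L, 3L * n1 - 1L, 3L * n1,
         3L * n2 - 1L, 3L * n2,
         3L * n3))
}

#' Assemble and factorize the substrate stiffness operator
#'
#' Builds the global trilinear-hexahedron stiffness matrix for an
#' isotropic linear-elastic substrate with free boundary surfaces,
#' suppresses the six rigid-body modes by the 3-2-1 corner rule, and
#' caches a sparse Cholesky factorization that is reused for every
#' sensing solve of a scenario.
#'
#' @param mesh a \code{substrate_mesh}.
#' @param mat a \code{material_props}.
#' @param keep_stiffness keep the unconstrained stiffness matrix in the
#'   returned object (used by tests; off by default to save memory).
#' @return object of class \code{fe_operator}.
#' @export
assemble_operator <- function(mesh, mat, keep_stiffness = FALSE) {
  stopifnot(inherits(mesh, "substrate_mesh"), inherits(mat, "material_props"))
  K <- assemble_stiffness(mesh, mat)
  fixed <- corner_constraints(mesh)
  free <- setdiff(seq_len(3L * mesh$n_nodes), fixed)
  Kff <- K[free, free]
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop("assembly error: constrained stiffness is not positive definite: ",
                        conditionMessage(e), call. = FALSE)
                 })
  op <- list(mesh = mesh, mat = mat, chol = ch, free = free,
             constrained_dofs = fixed, n_dof = 3L * mesh$n_nodes)
  if (keep_stiffness) op$K <- K
  structure(op, class = "fe_operator")
}

#' @export
print.fe_operator <- function(x, ...) {
  cat(sprintf("fe_operator: %d dof (%d constrained), E = %g kPa, nu = %g\n",
              x$n_dof, length(x$constrained_dofs), x$mat$E, x$mat$nu))
  invisible(x)
}

# Build a global load vector from point forces. pts: m x 3 positions (um),
# forces: m x 3 (nN). Forces are spread to the containing element's nodes
# with trilinear shape-function weights.
point_load_vector <- function(mesh, pts, forces, pw = NULL) {
  if (is.null(pw)) pw <- point_weights(mesh, pts)
  f <- numeric(3L * mesh$n_nodes)
  for (a in 1:8) {
    idx <- pw$nodes[, a]
    w <- pw$w[, a]
    f[3L * idx - 2L] <- f[3L * idx - 2L] + w * forces[, 1]
    f[3L * idx - 1L] <- f[3L * idx - 1L] + w * forces[, 2]
    f[3L * idx]      <- f[3L * idx]      + w * forces[, 3]
  }
  f
}

# Solve for the free DOFs given a full-length load vector.
solve_operator <- function(op, f) {
  u <- numeric(op$n_dof)
  u[op$free] <- as.numeric(Matrix::solve(op$chol, f[op$free], system = "A"))
  matrix(u, ncol = 3L, byrow = TRUE)
}

#' Solve substrate displacements under point sensing loads
#'
#' Distributes each point force to the nodes of its containing element by
#' trilinear shape-function weights, then solves the constrained linear
#' system with the cached factorization.
#'
#' @param op an \code{fe_operator}.
#' @param pts m x 3 matrix of load positions (um), inside the box.
#' @param forces m x 3 matrix of force vectors (nN).
#' @return n_nodes x 3 nodal displacement matrix (um).
#' @export
solve_displacements <- function(op, pts, forces) {
  pts <- matrix(pts, ncol = 3)
  forces <- matrix(forces, ncol = 3)
  stopifnot(nrow(pts) == nrow(forces))
  solve_operator(op, point_load_vector(op$mesh, pts, forces))
}
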