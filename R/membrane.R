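#' Membrane node template
#'
#' Deterministic, well-spread unit directions for the membrane nodes of
#' the spherical cell. The default 24-node template is the vertex set of
#' a rhombicuboctahedron: vertex-transitive with full octahedral
#' symmetry, antipodally symmetric (the directions sum to zero exactly)
#' and isotropic in second moments, so a cell probing a homogeneous
#' unbounded medium senses no spurious directional bias. Small counts map
#' to the platonic solids (4 tetrahedron, 6 octahedron, 8 cube, 12
#' icosahedron); other even counts use an antipodally symmetrized
#' spherical Fibonacci set.
#'
#' @param n_mem number of membrane nodes (>= 4; even for non-platonic counts).
#' @return n_mem x 3 matrix of unit row vectors.
#' @examples
#' e <- membrane_template(24)
#' max(abs(colSums(e)))  # ~ 0
#' @export
membrane_template <- function(n_mem = 24L) {
  n_mem <- as.integer(n_mem)
  if (is.na(n_mem) || n_mem < 4L) {
    stop("invalid config: n_mem must be an integer >= 4", call. = FALSE)
  }
  V <- switch(as.character(n_mem),
    "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    "8" = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    "12" = {
      phi <- (1 + sqrt(5)) / 2
      B <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi))
      rbind(B, B[, c(3, 1, 2)], B[, c(2, 3, 1)])
    },
    "24" = {
      xi <- 1 + sqrt(2)
      B <- rbind(c(1, 1, xi), c(1, -1, xi), c(-1, 1, xi), c(-1, -1, xi))
      V <- rbind(B, B[, c(3, 1, 2)], B[, c(2, 3, 1)])
      rbind(V, -V)
    },
    {
      if (n_mem %% 2L != 0L) {
        stop("invalid config: antipodally symmetric template needs even n_mem",
             call. = FALSE)
      }
      m <- n_mem %/% 2L
      i <- seq_len(m) - 0.5
      z <- 1 - i / m                       # upper hemisphere only
      th <- pi * (1 + sqrt(5)) * i
      H <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
      rbind(H, -H)
    }
  )
  V <- V / sqrt(rowSums(V^2))
  dimnames(V) <- NULL
  V
}
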