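test_that("membrane templates are unit, distinct, balanced and well spread", {
  e24 <- membrane_template(24)
  expect_equal(nrow(e24), 24L)
  expect_equal(sqrt(rowSums(e24^2)), rep(1, 24))
  expect_equal(nrow(unique(round(e24, 10))), 24L)
  expect_lt(max(abs(colSums(e24))), 1e-8)

  e6 <- membrane_template(6)
  expect_equal(sort(abs(rowSums(e6))), rep(1, 6))  # +/- axis vectors

  # isotropy of second moments (spherical 2-design property)
  expect_equal(crossprod(e24), diag(3) * 8, tolerance = 1e-10)

  # coverage radius no worse than typical random 24-point sets
  set.seed(42)
  probes <- matrix(rnorm(3 * 500), ncol = 3)
  probes <- probes / sqrt(rowSums(probes^2))
  coverage <- function(V) max(apply(probes, 1, function(p)
    min(acos(pmin(pmax(V %*% p, -1), 1)))))
  cov_template <- coverage(e24)
  cov_random <- replicate(100, {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    V <- matrix(rnorm(72), ncol = 3)
    coverage((V / sqrt(rowSums(V^2))) %*% R)
  })
  expect_lt(cov_template, stats::median(cov_random))

  # generic even count: antipodal Fibonacci
  e10 <- membrane_template(10)
  expect_lt(max(abs(colSums(e10))), 1e-12)
  expect_error(membrane_template(3), "invalid config")
  expect_error(membrane_template(11), "invalid config")
})

test_that("cell stress law evaluates its branches and stays continuous", {
  p <- mechanical_params()
  # outside the working range: passive only
  expect_equal(cell_stress(1.0, p), 2.8)
  expect_equal(cell_stress(-0.95, p), 2.8 * -0.95)
  # at zero strain: active branch value
  expect_equal(cell_stress(0, p),
               p$K_act * p$sigma_max * p$eps_min /
                 (p$K_act * p$eps_min - p$sigma_max))
  expect_equal(cell_stress(0, p), 0.0947368421, tolerance = 1e-9)
  # peak: both active branches agree with sigma_max + K_pas * eps_tilde
  et <- p$sigma_max / p$K_act
  expect_equal(cell_stress(et, p), 0.24)
  expect_equal(cell_stress(et - 1e-13, p), cell_stress(et + 1e-13, p),
               tolerance = 1e-10)

  # continuity at all three breakpoints for random valid parameter sets
  set.seed(1)
  for (k in 1:20) {
    q <- mechanical_params(K_pas = runif(1, 0.5, 5), K_act = runif(1, 0.5, 5),
                           eps_min = -runif(1, 0.3, 1.5),
                           eps_max = runif(1, 0.3, 1.5),
                           sigma_max = runif(1, 0.01, 0.2))
    for (bp in c(q$eps_min, q$sigma_max / q$K_act, q$eps_max)) {
      gap <- abs(cell_stress(bp - 1e-9, q) - cell_stress(bp + 1e-9, q))
      expect_lt(gap, 1e-7)  # slope-bounded jump => continuous
    }
    # exact two-sided limits via branch coefficients
    br <- mechanofate:::stress_branches(c(q$eps_min - 1e-15, q$eps_min + 1e-15), q)
    expect_lt(abs(diff(br$a + br$b * q$eps_min)), 1e-12)
  }
})

test_that("adhesivity is the binding product and the traction split uses its ratio", {
  expect_equal(adhesivity(1e8, 1.5e5, 1e-5), 1.5e8)
  expect_equal(adhesivity(1e8, 1e5, 1e-5), 1.0e8)
  expect_equal(adhesivity(1e8, 1e5, 0), 0)

  p <- mechanical_params()
  cl <- cell_state(1, c(100, 100, 100), "MSC", p)
  cl$node_strain <- rep(0.01, p$n_mem)

  # equal front/back receptors: symmetric template cancels exactly
  p_eq <- mechanical_params(n_rf = 1e5, n_rb = 1e5)
  tr <- traction_forces(cl, p_eq, e_pol_prev = c(1, 0, 0))
  expect_lt(sqrt(sum(tr$net^2)), 1e-9)
  # per-node magnitude is sigma * S_node at unit relative adhesivity
  sig <- cell_stress(-0.01, p_eq)
  expect_equal(sqrt(rowSums(tr$forces^2)),
               rep(sig * 4 * pi * p$r_cell^2 / 24, 24))

  # reference front/back asymmetry: net is parallel to prior polarisation
  e_pol <- c(1, 0, 0)
  tr2 <- traction_forces(cl, p, e_pol_prev = e_pol)
  nrm <- sqrt(sum(tr2$net^2))
  expect_gt(nrm, 0)
  expect_equal(sum(tr2$net * e_pol) / nrm, 1, tolerance = 1e-9)

  # a node at stress 0.1 kPa carries |F| = 0.1 * S_node ~ 20.9 nN
  x01 <- (0.1 - cell_stress(0, p_eq)) /
    (cell_stress(0.01, p_eq) - cell_stress(0, p_eq)) * 0.01  # sigma(x01) = 0.1
  cl$node_strain <- rep(-x01, p$n_mem)
  tr3 <- traction_forces(cl, p_eq)
  expect_equal(sqrt(sum(tr3$forces[1, ]^2)), 0.1 * 209.4395102, tolerance = 1e-6)
})

test_that("protrusion force is bounded, uniform in magnitude and isotropic", {
  set.seed(11)
  F <- c(2, -1, 0.5)
  nF <- sqrt(sum(F^2))
  expect_equal(protrusion_force(c(0, 0, 0)), c(0, 0, 0))
  n <- 20000
  draws <- t(replicate(n, protrusion_force(F)))
  ratio <- sqrt(rowSums(draws^2)) / nF
  expect_true(all(ratio < 1))
  ks <- suppressWarnings(stats::ks.test(ratio, "punif"))
  expect_gt(ks$p.value, 0.01)
  dirs <- draws / sqrt(rowSums(draws^2))
  expect_lt(sqrt(sum(colMeans(dirs)^2)), 0.02)
})

test_that("force balance closes exactly and follows the Stokes drag law", {
  p <- mechanical_params()
  mat <- material_props(45)
  fb <- resolve_motion(c(1, 0, 0), c(0, 0, 0), p, mat)
  expect_equal(fb$F_drag, c(-1, 0, 0))
  expect_equal(fb$e_pol, c(1, 0, 0))
  expect_lt(max(abs(fb$F_trac_net + fb$F_prot + fb$F_drag)), 1e-9)

  # |F_drag| = 0.105 nN, r = 20 um, eta = 1000 Pa s -> v ~ 1.0 um/h
  fb2 <- resolve_motion(c(0.105, 0, 0), c(0, 0, 0), p, mat)
  expect_equal(fb2$v, 0.105 * 3600 / (6 * pi * 20 * 1000 * 1e-3),
               tolerance = 1e-12)
  expect_equal(fb2$v, 1.0, tolerance = 5e-3)

  # doubling viscosity halves speed and step exactly
  fb3 <- resolve_motion(c(0.105, 0, 0), c(0, 0, 0), p, material_props(45, eta = 2000))
  expect_equal(fb3$v, fb2$v / 2)
  expect_equal(fb3$d, fb2$d / 2)

  # zero drag: previous polarisation kept, no translocation
  fb4 <- resolve_motion(c(0, 0, 0), c(0, 0, 0), p, mat, e_pol_prev = c(0, 1, 0))
  expect_equal(fb4$e_pol, c(0, 1, 0))
  expect_equal(fb4$d, c(0, 0, 0))
})

test_that("mechano-sensing vanishes on a rigid substrate and is self-consistent", {
  p <- mechanical_params()
  m <- small_mesh()
  op_rigid <- assemble_operator(m, material_props(1e6))
  cl <- cell_state(1, c(60, 40, 40), "MSC", p)
  cl <- mechanosense(cl, op_rigid, p)
  expect_true(cl$sense_converged)
  expect_lt(max(abs(cl$node_strain)), 1e-4)

  op <- small_operator(20)
  cl2 <- mechanosense(cell_state(1, c(60, 40, 40), "MSC", p), op, p)
  expect_true(cl2$sense_converged)
  # re-applying one explicit fixed-point sweep changes eps by < 1e-6:
  # recompute forces from converged eps and resolve once
  sig <- cell_stress(-cl2$node_strain, p)
  S <- 4 * pi * p$r_cell^2 / p$n_mem
  pts <- sweep(p$r_cell * cl2$membrane_dirs, 2, cl2$centroid, `+`)
  u <- solve_displacements(op, pts, -sig * S * cl2$membrane_dirs)
  eps_again <- rowSums(mechanofate:::interp_at_points(op$mesh, u, pts) *
                         (-cl2$membrane_dirs)) / p$r_cell
  expect_lt(max(abs(eps_again - cl2$node_strain)), 1e-6)
  # stored tensors are symmetric
  for (i in c(1, 7, 24)) {
    expect_equal(cl2$node_tensor[i, , ], t(cl2$node_tensor[i, , ]))
  }
})

test_that("a centred cell senses a near-symmetric strain distribution", {
  p <- mechanical_params()
  m <- build_hex_mesh(c(80, 80, 80), c(8, 8, 8))
  op <- assemble_operator(m, material_props(20))
  cl <- mechanosense(cell_state(1, c(40, 40, 40), "MSC", p), op, p)
  eps <- abs(cl$node_strain)
  expect_lt(stats::sd(eps) / mean(eps), 0.05)
})

test_that("sensed deformation decreases monotonically with substrate stiffness", {
  p <- mechanical_params()
  m <- build_hex_mesh(c(120, 80, 80), c(12, 8, 8))
  meas <- vapply(c(0.1, 1, 20, 25, 30, 45), function(E) {
    op <- assemble_operator(m, material_props(E))
    cl <- mechanosense(cell_state(1, c(60, 40, 40), "MSC", p), op, p)
    mean(abs(cl$node_strain))
  }, numeric(1))
  expect_true(all(diff(meas) < 0))
})

test_that("out-of-domain membrane nodes raise an error", {
  p <- mechanical_params()
  op <- small_operator(45)
  cl <- cell_state(1, c(5, 40, 40), "MSC", p)  # sphere pokes out of the box
  expect_error(mechanosense(cl, op, p), "out of domain")
})
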