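# Projection-solver building blocks and steady solves on analytic fixtures.

test_that("domain assembly pads all-fluid buffers along the flow axis", {
  f <- array(runif(20^3) > 0.3, c(20, 20, 20)) * 1
  fld <- fraction_field(f, 36)
  bc <- flow_bc(1e-5, "x", buffer_upstream = 10, buffer_downstream = 10)
  dom <- assemble_domain(fld, bc)
  expect_equal(dim(dom$f), c(40, 20, 20))
  expect_true(all(dom$f[1:10, , ] == 1))
  expect_true(all(dom$f[31:40, , ] == 1))
  expect_identical(dom$f[11:30, , ], fld$f)          # scaffold unchanged
  expect_equal(attr(dom, "scaffold_range"), c(11, 30))

  bcz <- flow_bc(1e-5, "z", buffer_upstream = 3, buffer_downstream = 4)
  domz <- assemble_domain(fld, bcz)
  expect_equal(dim(domz$f), c(20, 20, 27))
  expect_identical(domz$f[, , 4:23], fld$f)
})

test_that("momentum step fixes zero and uniform fields", {
  fld <- fraction_field(array(1, c(6, 6, 10)), 36)
  props <- standard_props()
  zero <- list(u = array(0, c(7, 6, 10)), v = array(0, c(6, 7, 10)),
               w = array(0, c(6, 6, 11)))
  us <- advance_momentum(zero, fld, props, 1e-5, inflow_velocity = 0)
  expect_equal(max(abs(us$us)), 0)
  expect_equal(max(abs(us$vs)), 0)
  expect_equal(max(abs(us$ws)), 0)

  # uniform axial flow in an all-fluid duct: convection and diffusion of a
  # constant field vanish (free-slip lateral ghosts)
  U <- 3e-5
  unif <- list(u = array(0, c(7, 6, 10)), v = array(0, c(6, 7, 10)),
               w = array(U, c(6, 6, 11)))
  us2 <- advance_momentum(unif, fld, props, 1e-5, inflow_velocity = U)
  expect_equal(us2$ws, unif$w, tolerance = 1e-12)

  expect_error(advance_momentum(unif, fld, props, 1), "stability")
})

test_that("one momentum step decays a transverse mode like the heat equation", {
  # w = cos(pi x / Lx), uniform elsewhere: a pure-diffusion eigenmode of
  # the free-slip Laplacian; one explicit step must match exp(-nu k^2 dt)
  # to first order in dt
  nx <- 32; props <- standard_props()
  fld <- fraction_field(array(1, c(nx, 4, 8)), 36)
  h <- 36e-6
  nu <- props$viscosity / props$density
  amp <- 1e-5
  x <- (seq_len(nx) - 0.5) / nx
  w <- array(rep(amp * cos(pi * x), times = 4 * 9), c(nx, 4, 9))
  st <- list(u = array(0, c(nx + 1, 4, 8)), v = array(0, c(nx, 5, 8)), w = w)
  dt <- 0.2 * h^2 / (6 * nu)
  us <- advance_momentum(st, fld, props, dt, inflow_velocity = 0)
  k2 <- (pi / (nx * h))^2
  ratio <- sum(us$ws[, 1, 5] * w[, 1, 5]) / sum(w[, 1, 5]^2)
  expect_equal(ratio, exp(-nu * k2 * dt), tolerance = 1e-4)
})

test_that("pressure solve matches a directly assembled 1D system", {
  # uniform inflow into an open 1 x 1 x n column: compare against the
  # exact solve of the same tridiagonal operator
  n <- 16; h <- 36e-6; dt <- 1e-4
  props <- standard_props()
  fld <- fraction_field(array(1, c(1, 1, n)), 36)
  vin <- 2e-5
  us <- list(us = array(0, c(2, 1, n)), vs = array(0, c(1, 2, n)),
             ws = array(c(vin, rep(0, n)), c(1, 1, n + 1)))
  p <- solve_pressure_poisson(us, fld, props, dt)
  expect_lt(attr(p, "relative_residual"), 1e-8)
  # direct tridiagonal assembly of div(grad P) = (rho/dt) div(u*)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) { A[i, i] <- A[i, i] + 1; A[i, i - 1] <- -1 }
    if (i < n) { A[i, i] <- A[i, i] + 1; A[i, i + 1] <- -1 }
    else A[i, i] <- A[i, i] + 2     # outlet Dirichlet at the face
  }
  b <- rep(0, n); b[1] <- props$density * h * vin / dt
  expect_equal(as.numeric(p), as.numeric(solve(A, b)), tolerance = 1e-6)
})

test_that("pressure operator is symmetric positive definite on fluid cells", {
  set.seed(3)
  f <- array(1, c(5, 5, 5)); f[2, 3, 2] <- 0; f[4, 2, 4] <- 0
  fld <- fraction_field(f, 36)
  props <- standard_props()
  dt <- 1e-4
  apply_A <- function(x) {
    # recover A x from the solver itself: projecting u* = 0 with pressure
    # x leaves div(u) = (dt / (rho h^2)) [A x]
    us0 <- list(us = array(0, c(6, 5, 5)), vs = array(0, c(5, 6, 5)),
                ws = array(0, c(5, 5, 6)))
    pr <- project_velocity(us0, array(x, dim(f)), fld, props, dt)
    velocity_divergence(pr, fld) * props$density * (36e-6)^2 / dt
  }
  n <- length(f)
  cols <- vapply(seq_len(n), function(i) {
    e <- rep(0, n); e[i] <- 1
    as.numeric(apply_A(e))
  }, numeric(n))
  fluid <- as.numeric(f) > 0
  Af <- cols[fluid, fluid]
  expect_equal(Af, t(Af), tolerance = 1e-10)
  ev <- eigen(Af, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))   # strictly positive: outlet Dirichlet present
})

test_that("projection is exact and produces a divergence-free field", {
  props <- standard_props()
  # f = 1 and constant P: u = u*
  fld <- fraction_field(array(1, c(6, 6, 6)), 36)
  set.seed(5)
  us <- list(us = array(rnorm(7 * 6 * 6, sd = 1e-5), c(7, 6, 6)),
             vs = array(rnorm(6 * 7 * 6, sd = 1e-5), c(6, 7, 6)),
             ws = array(rnorm(6 * 6 * 7, sd = 1e-5), c(6, 6, 7)))
  pr <- project_velocity(us, array(0, c(6, 6, 6)), fld, props, 1e-4)
  expect_identical(pr$u[2:6, , ], us$us[2:6, , ])

  # random u* in a 10^3 all-fluid box: post-projection divergence is tiny
  fld10 <- fraction_field(array(1, c(10, 10, 10)), 36)
  set.seed(6)
  us10 <- list(us = array(rnorm(11 * 100, sd = 2e-6), c(11, 10, 10)),
               vs = array(rnorm(11 * 100, sd = 2e-6), c(10, 11, 10)),
               ws = array(rnorm(11 * 100, sd = 2e-6), c(10, 10, 11)))
  p <- solve_pressure_poisson(us10, fld10, props, 1e-4, rtol = 1e-12)
  pr10 <- project_velocity(us10, p, fld10, props, 1e-4)
  div <- velocity_divergence(pr10, fld10)
  expect_lt(max(abs(div)), 1e-8 * 2e-5 / 36e-6)

  # a solid voxel forces all six adjacent face velocities to zero
  f <- array(1, c(5, 5, 5)); f[3, 3, 3] <- 0
  flds <- fraction_field(f, 36)
  us5 <- list(us = array(rnorm(6 * 25, sd = 1e-5), c(6, 5, 5)),
              vs = array(rnorm(6 * 25, sd = 1e-5), c(5, 6, 5)),
              ws = array(rnorm(6 * 25, sd = 1e-5), c(5, 5, 6)))
  prs <- project_velocity(us5, array(0, c(5, 5, 5)), flds,
                          props, 1e-4)
  expect_equal(prs$u[3, 3, 3], 0)
  expect_equal(prs$u[4, 3, 3], 0)
  expect_equal(prs$v[3, 3, 3], 0)
  expect_equal(prs$v[3, 4, 3], 0)
  expect_equal(prs$w[3, 3, 3], 0)
  expect_equal(prs$w[3, 3, 4], 0)
})

test_that("an empty duct carries plug flow and conserves the flow rate", {
  fld <- fraction_field(array(1, c(8, 8, 24)), 36)
  bc <- flow_bc(2e-5, "z", buffer_upstream = 4, buffer_downstream = 4)
  st <- solve_steady_flow(fld, bc, standard_props(), tol = 1e-8)
  expect_true(st$converged)
  # free-slip walls: the flat inlet profile is already the solution
  expect_equal(max(abs(st$w - 2e-5)), 0, tolerance = 1e-10)
  # flow rate identical across every cross-section
  q <- apply(st$w, 3, sum)
  expect_lt(max(abs(q - q[1])) / q[1], 1e-3 / 100)
})

test_that("plane-channel flow reproduces the Poiseuille profile", {
  fld <- make_fixture("plane_channel", c(4, 26, 80), gap = 20)
  bc <- flow_bc(2e-5, "z", buffer_upstream = 2, buffer_downstream = 2)
  st <- solve_steady_flow(fld, bc, standard_props())
  prof <- axial_profile(st, fld)
  fluid_rows <- which(fld$f[2, , 1] > 0)
  vals <- prof[fluid_rows]
  expect_equal(max(vals) / mean(vals), 1.5, tolerance = 0.05)
  mc <- check_mass_conservation(st, fld)
  expect_lt(mc$imbalance, 0.005)
})

test_that("a blocked domain raises a blocked-domain error", {
  f <- array(1, c(6, 6, 12)); f[, , 6] <- 0   # solid wall across the duct
  fld <- fraction_field(f, 36)
  bc <- flow_bc(2e-5, "z", buffer_upstream = 2, buffer_downstream = 2)
  expect_error(solve_steady_flow(fld, bc, standard_props()),
               "blocked domain")
})

test_that("flow along x and z axes give the same physics", {
  f <- array(1, c(20, 8, 8)); f[8:12, 3:6, ] <- 0
  # a partial obstruction; rotate the same geometry to the z axis
  fldx <- fraction_field(f, 36)
  fldz <- fraction_field(aperm(f, c(2, 3, 1)), 36)
  bx <- flow_bc(2e-5, "x", buffer_upstream = 3, buffer_downstream = 3)
  bz <- flow_bc(2e-5, "z", buffer_upstream = 3, buffer_downstream = 3)
  sx <- solve_steady_flow(assemble_domain(fldx, bx), bx, standard_props())
  sz <- solve_steady_flow(assemble_domain(fldz, bz), bz, standard_props())
  expect_equal(max(sx$u), max(sz$w), tolerance = 1e-10)
  expect_equal(range(sx$p), range(sz$p), tolerance = 1e-8)
})
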