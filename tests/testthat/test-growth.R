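# Shear evaluation, growth-site identification and the windowed growth law.

test_that("shear magnitude recovers an imposed uniform shear rate", {
  # u = gamma * y, v = w = 0: tau = mu * gamma everywhere in the bulk
  gamma <- 100; mu <- 8.4e-4
  d <- c(8, 12, 8); h <- 36e-6
  fld <- fraction_field(array(1, d), 36)
  ycent <- (seq_len(d[2]) - 0.5) * h
  u <- array(rep(rep(gamma * ycent, each = d[1] + 1), d[3]),
             c(d[1] + 1, d[2], d[3]))
  st <- list(u = u, v = array(0, d + c(0, 1, 0)),
             w = array(0, d + c(0, 0, 1)),
             props = list(viscosity = mu))
  sh <- compute_shear_field(st, fld, viscosity = mu)
  interior <- sh$tau[3:6, 3:10, 3:6]
  expect_equal(as.numeric(interior), rep(mu * gamma, length(interior)),
               tolerance = 1e-12)
  expect_equal(max(abs(sh$ty)), 0)
  expect_equal(max(abs(sh$tz[3:6, 3:10, 3:6])), 0)
})

test_that("zero velocity gives zero shear", {
  d <- c(6, 6, 6)
  fld <- fraction_field(array(1, d), 36)
  st <- list(u = array(0, d + c(1, 0, 0)), v = array(0, d + c(0, 1, 0)),
             w = array(0, d + c(0, 0, 1)), props = list(viscosity = 8.4e-4))
  sh <- compute_shear_field(st, fld)
  expect_equal(max(sh$tau), 0)
})

test_that("wall-adjacent shear matches plane Poiseuille", {
  fld <- make_fixture("plane_channel", c(4, 26, 80), gap = 20)
  bc <- flow_bc(2e-5, "z", buffer_upstream = 2, buffer_downstream = 2)
  props <- standard_props()
  st <- solve_steady_flow(fld, bc, props)
  sh <- compute_shear_field(st, fld)
  fluid_rows <- which(fld$f[2, , 1] > 0)
  prof <- axial_profile(st, fld)
  u_mean <- mean(prof[fluid_rows])
  h_gap <- 20 * 36e-6
  tau_wall <- sh$tau[2, fluid_rows[1], 40]
  expect_equal(tau_wall, 6 * props$viscosity * u_mean / h_gap,
               tolerance = 0.15)
})

test_that("growth sites track the fluid-material interface", {
  d <- c(3, 3, 3)
  # all fluid: no sites
  expect_false(any(identify_growth_sites(fraction_field(array(1, d), 36))))
  # single solid voxel: exactly its six face neighbours
  f <- array(1, c(5, 5, 5)); f[3, 3, 3] <- 0
  sites <- identify_growth_sites(fraction_field(f, 36))
  expect_equal(sum(sites), 6)
  expect_true(sites[2, 3, 3] && sites[4, 3, 3] && sites[3, 2, 3] &&
              sites[3, 4, 3] && sites[3, 3, 2] && sites[3, 3, 4])
  expect_false(sites[3, 3, 3])   # the solid voxel itself is not a site

  # two-step advance: once a site fills to f = 0, its fluid neighbours
  # (previously non-sites) become sites
  f2 <- array(1, c(5, 5, 5)); f2[1, 3, 3] <- 0
  fld2 <- fraction_field(f2, 36)
  s1 <- identify_growth_sites(fld2)
  expect_true(s1[2, 3, 3]); expect_false(s1[3, 3, 3])
  tau <- array(1e-3, c(5, 5, 5))
  sh <- manual_shear_field(tau, s1)
  # huge growth factor + rate cap 1: the site fills in a single step
  params <- growth_parameters(growth_factor = 1e6, max_growth_rate = 1)
  g1 <- growth_step(fld2, sh, params, 1e4)
  expect_equal(g1$f[2, 3, 3], 0)
  s2 <- identify_growth_sites(g1)
  expect_true(s2[3, 3, 3])   # the front advanced
})

test_that("growth law applies the shear window, rate cap and clamping", {
  params <- growth_parameters()  # A = 1.5e-4, window 0.05..56 mPa
  d <- c(2, 2, 2)
  fld <- fraction_field(array(1, d), 36)
  mk <- function(tau_val) manual_shear_field(array(tau_val, d))
  dt <- 1000

  # below the critical shear: no growth
  g <- growth_step(fld, mk(3e-5), params, dt)
  expect_identical(g$f, fld$f)
  # exactly at the window edges growth is active (cutoff is strict)
  g_lo <- growth_step(fld, mk(5e-5), params, dt)
  expect_true(all(g_lo$f < 1))
  g_hi <- growth_step(fld, mk(5.6e-2), params, dt)
  expect_true(all(g_hi$f < 1))
  # above the maximum with the constraint on: no growth
  g_over <- growth_step(fld, mk(6e-2), params, dt)
  expect_identical(g_over$f, fld$f)
  # ... with the constraint off: growth at the capped rate
  params_off <- growth_parameters(enforce_max_constraint = FALSE)
  g_off <- growth_step(fld, mk(6e-2), params_off, dt)
  expect_equal(g_off$f[1, 1, 1],
               1 - min(1.5e-4 * 6e-2, 1.5e-5) * dt)

  # dG = A tau dt in the linear range
  g_lin <- growth_step(fld, mk(1e-2), params, dt)
  expect_equal(g_lin$f[1, 1, 1], 1 - 1.5e-3)
  # dt = 0 leaves the field unchanged
  expect_identical(growth_step(fld, mk(1e-2), params, 0)$f, fld$f)
  # f clamps at zero
  fsmall <- fraction_field(array(1e-4, d), 36)
  expect_equal(min(growth_step(fsmall, mk(1e-2), params, 1e5)$f), 0)
  expect_error(growth_step(fld, mk(1e-2), params, -1), "dt")
})

test_that("vectorized growth agrees bit-exactly with the voxelwise oracle", {
  set.seed(91)
  for (rep in 1:3) {
    f <- array(runif(125), c(5, 5, 5))
    f[sample(125, 20)] <- 0
    f[sample(125, 20)] <- 1
    fld <- fraction_field(f, 36)
    tau <- array(10^runif(125, -5, 0), c(5, 5, 5))
    sh <- manual_shear_field(tau, identify_growth_sites(fld))
    params <- growth_parameters(enforce_max_constraint = rep %% 2 == 0)
    fast <- growth_step(fld, sh, params, 3600)
    slow <- reference_growth_step(fld, sh, params, 3600)
    expect_identical(fast$f, slow$f)
  }
})

test_that("growth is monotone and windows behave as dominance relations", {
  set.seed(14)
  f <- array(runif(216, 0.2, 1), c(6, 6, 6))
  fld <- fraction_field(f, 36)
  tau <- array(10^runif(216, -5, -0.5), c(6, 6, 6))
  sh <- manual_shear_field(tau, identify_growth_sites(fld))
  params_on <- growth_parameters()
  params_off <- growth_parameters(enforce_max_constraint = FALSE)
  g_on <- growth_step(fld, sh, params_on, 7200)
  g_off <- growth_step(fld, sh, params_off, 7200)
  # f never increases
  expect_true(all(g_on$f <= fld$f))
  # removing the max constraint never decreases growth anywhere
  expect_true(all(g_off$f <= g_on$f))
  # tau_min above all observed shear: identically zero growth
  params_dead <- growth_parameters(tau_min = 10, tau_max = 20)
  expect_identical(growth_step(fld, sh, params_dead, 7200)$f, fld$f)
})

test_that("coupled runs: no inflow, no growth; growth matches bookkeeping", {
  fld <- small_scaffold(2)
  bc <- flow_bc(0, "z", buffer_upstream = 4, buffer_downstream = 4)
  dom <- assemble_domain(fld, bc)
  params <- growth_parameters(macro_dt = 3600)
  hist0 <- run_coupled_simulation(dom, bc, standard_props(), params,
                                  total_time = 2 * 3600,
                                  snapshot_times = numeric(0))
  expect_equal(max(hist0$series$growth_pct), 0)

  bc2 <- flow_bc(2e-4, "z", buffer_upstream = 4, buffer_downstream = 4)
  dom2 <- assemble_domain(fld, bc2)
  params2 <- growth_parameters(macro_dt = 7200,
                               enforce_max_constraint = FALSE)
  hist <- run_coupled_simulation(dom2, bc2, standard_props(), params2,
                                 total_time = 4 * 7200,
                                 snapshot_times = numeric(0))
  g <- hist$series$growth_pct
  expect_true(all(diff(g) >= 0))                   # non-decreasing
  expect_lte(max(g), 100)
  expect_gt(max(g), 0)
  # growth_volume_fraction == time-integral of applied deposition
  f0 <- sum(perfusim:::scaffold_region(hist$initial_field))
  expect_equal(max(g), 100 * hist$deposited_total / f0, tolerance = 1e-12)
})
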