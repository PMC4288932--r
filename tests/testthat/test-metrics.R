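# Shear statistics, distribution moments, growth accounting and the flow
# summary / permeability.

test_that("distribution moments use population sd, skew and excess kurtosis", {
  # symmetric two-point sample
  m <- distribution_moments(c(1, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$skew, 0)
  expect_equal(m$sd, 1)   # population convention

  set.seed(21)
  u <- runif(1e6)
  mu <- distribution_moments(u)
  expect_equal(mu$kurtosis, -1.2, tolerance = 0.02)  # 9/5 - 3
  expect_equal(mu$skew, 0, tolerance = 0.01)

  g <- rnorm(1e6)
  mg <- distribution_moments(g)
  expect_equal(mg$skew, 0, tolerance = 0.02)
  expect_equal(mg$kurtosis, 0, tolerance = 0.03)

  # closed-form log-normal moments
  ln <- rlnorm(1e5, meanlog = -5, sdlog = 0.8)
  ml <- distribution_moments(ln)
  expect_equal(ml$mean, exp(-5 + 0.8^2 / 2), tolerance = 0.02)
  expect_equal(ml$sd, sqrt((exp(0.8^2) - 1) * exp(-10 + 0.8^2)),
               tolerance = 0.04)

  expect_error(distribution_moments(1), "at least 2")
  dg <- distribution_moments(c(2, 2, 2))
  expect_true(dg$degenerate)
  expect_equal(dg$skew, 0)
})

test_that("shear histogram conserves mass and flags degenerate input", {
  d <- c(6, 6, 6)
  fld <- fraction_field(array(1, d), 36)
  interface <- array(FALSE, d); interface[2:5, 2:5, 3] <- TRUE
  tau <- array(0, d); tau[interface] <- 1e-2
  sh <- manual_shear_field(tau, interface)
  hist <- shear_histogram(sh, fld)
  # point mass: mean = mode = 10 mPa (mode to within one log bin), sd = 0
  expect_equal(hist$mean, 1e-2)
  expect_equal(hist$mode, 1e-2, tolerance = 0.06)
  expect_equal(hist$sd, 0)
  expect_true(hist$degenerate)
  expect_equal(hist$skew, 0)
  # counts sum to the number of in-range interface voxels
  expect_equal(sum(hist$counts), sum(interface))
  # density integrates (in dlog10 tau) to counts / fluid volume
  dlog <- diff(log10(hist$breaks))
  expect_equal(sum(hist$density * dlog), sum(interface) / hist$fluid_volume)

  # moments are invariant to the binning choice
  set.seed(8)
  tau[interface] <- 10^runif(sum(interface), -4, -1)
  sh2 <- manual_shear_field(tau, interface)
  h1 <- shear_histogram(sh2, fld, bins_per_decade = 40)
  h2 <- shear_histogram(sh2, fld, bins_per_decade = 13)
  expect_identical(h1$mean, h2$mean)
  expect_identical(h1$sd, h2$sd)
  expect_identical(h1$skew, h2$skew)
  expect_identical(h1$kurtosis, h2$kurtosis)

  expect_error(shear_histogram(manual_shear_field(tau, array(FALSE, d)),
                               fld), "empty interface")
})

test_that("growth volume fraction measures consumed fluid fraction", {
  d <- c(4, 4, 4)
  f0 <- fraction_field(array(1, d), 36)
  expect_equal(growth_volume_fraction(f0, f0), 0)
  half <- fraction_field(array(0.5, d), 36)
  expect_equal(growth_volume_fraction(half, f0), 50)
  expect_error(growth_volume_fraction(
    fraction_field(array(1, c(3, 3, 3)), 36), f0), "different grids")
})

test_that("overall growth rate averages interval slopes", {
  lin <- data.frame(time_s = c(0, 100, 200), growth_pct = c(0, 1, 2))
  expect_equal(overall_growth_rate(lin), 1e-4)   # 1%/100 s as fraction/s
  zero <- data.frame(time_s = c(0, 100), growth_pct = c(0, 0))
  expect_equal(overall_growth_rate(zero), 0)
  # concave 3-point trajectory: mean of the two interval slopes
  conc <- data.frame(time_s = c(0, 100, 200), growth_pct = c(0, 3, 4))
  expect_equal(overall_growth_rate(conc), mean(c(3, 1) / 100) / 100)
  expect_gt(overall_growth_rate(conc), 1e-4)   # between the two slopes
  expect_lt(overall_growth_rate(conc), 3e-4)
  expect_error(overall_growth_rate(lin[1, , drop = FALSE]), "2 time points")
})

test_that("flow summary flags undefined permeability in an empty duct", {
  fld <- fraction_field(array(1, c(6, 6, 10)), 36)
  bc <- flow_bc(2e-5, "z", buffer_upstream = 2, buffer_downstream = 2)
  dom <- assemble_domain(fld, bc)
  st <- solve_steady_flow(dom, bc, standard_props())
  fs <- flow_summary(st, dom)
  expect_false(fs$permeability_defined)   # plug flow, zero pressure drop
  expect_true(is.na(fs$permeability))
  expect_equal(fs$max_axial_velocity, 2e-5, tolerance = 1e-6)
})

test_that("tube permeability matches the Hagen-Poiseuille equivalent", {
  R <- 8
  fld <- make_fixture("tube", c(24, 24, 24), radius = R)
  bc <- flow_bc(2e-5, "z", buffer_upstream = 4, buffer_downstream = 4)
  dom <- assemble_domain(fld, bc)
  props <- standard_props()
  st <- solve_steady_flow(dom, bc, props)
  fs <- flow_summary(st, dom)
  # k = (pi R^4 / 8) / A_cross for a single tube across section A_cross
  h <- 36e-6
  k_ana <- pi * (R * h)^4 / 8 / (24 * 24 * h^2)
  expect_equal(fs$permeability, k_ana, tolerance = 0.15)
  # permeability is independent of v_in in the creeping regime
  bc2 <- flow_bc(4e-5, "z", buffer_upstream = 4, buffer_downstream = 4)
  st2 <- solve_steady_flow(dom, bc2, props)
  fs2 <- flow_summary(st2, dom, bc2, props)
  expect_equal(fs2$permeability, fs$permeability, tolerance = 0.01)
})
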