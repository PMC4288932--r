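# Shared helpers: small geometries and reference solutions built in code.

standard_props <- function() fluid_properties(1009, 8.4e-4)

# A small calibrated regular scaffold (cached per session: the lattice and
# voxelization are deterministic).
small_scaffold <- local({
  cache <- NULL
  function(n = 2, porosity = 0.675) {
    key <- sprintf("%d_%g", n, porosity)
    if (is.null(cache[[key]])) {
      lat <- build_regular_lattice(rep(n, 3), 600)
      r <- calibrate_kernel_radius(lat, porosity, 0.005, 36, 50)
      cache[[key]] <<- attr(r, "field")
    }
    cache[[key]]
  }
})

# Brute-force growth step: voxel-by-voxel loop, no vectorization.
reference_growth_step <- function(field, shear, params, dt) {
  f <- field$f
  d <- dim(f)
  out <- f
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!shear$interface[i, j, k]) next
    tau <- shear$tau[i, j, k]
    rate <- min(params$growth_factor * tau, params$max_growth_rate)
    if (tau < params$tau_min) rate <- 0
    if (params$enforce_max_constraint && tau > params$tau_max) rate <- 0
    out[i, j, k] <- max(f[i, j, k] - rate * dt, 0)
  }
  res <- field
  res$f <- out
  res
}

# Construct a shear_field by hand (for growth-law unit tests).
manual_shear_field <- function(tau, interface = NULL) {
  d <- dim(tau)
  structure(list(tx = tau, ty = array(0, d), tz = array(0, d), tau = tau,
                 interface = if (is.null(interface)) array(TRUE, d) else
                   interface,
                 viscosity = 8.4e-4),
            class = "shear_field")
}

# Mid-domain axial velocity profile across y for a channel-like fixture.
axial_profile <- function(state, field, i = 2) {
  d <- dim(field$f)
  kmid <- d[3] %/% 2
  wcc <- 0.5 * (state$w[, , kmid] + state$w[, , kmid + 1])
  wcc[i, ]
}
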