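# Quantitative characterization of shear and growth fields: log-binned
# histograms, distribution moments, growth volume fraction, flow summary
# and Darcy permeability.

#' Fluid-volume-normalized log-binned shear histogram
#'
#' Counts the shear-stress magnitudes of all interface (growth-site)
#' voxels into logarithmically spaced bins and normalizes by the total
#' fluid volume: the reported density is counts per log10-decade of shear
#' per m^3 of fluid, so that the integral over log10(tau) equals the
#' number of counted voxels divided by the fluid volume. The mode is the
#' geometric centre of the highest-density bin. Moments are computed from
#' the raw (unbinned) interface values and are therefore invariant to the
#' binning choice.
#'
#' @param shear a `shear_field` from [compute_shear_field()].
#' @param field the [fraction_field()] the shear was computed on.
#' @param bins_per_decade log-bin resolution (default 40).
#' @param range shear range covered by the bins, in Pa (default
#'   `c(1e-6, 10)`; interface values outside the range are not counted,
#'   though they still enter the unbinned moments).
#' @return A list of class `shear_statistics`: `breaks` (Pa), `density`,
#'   `counts`, `mode` (Pa), `mean`, `sd`, `skew`, `kurtosis`,
#'   `fluid_volume` (m^3), `n` and a `degenerate` flag (all interface
#'   shear values identical, e.g. all zero).
#' @export
shear_histogram <- function(shear, field, bins_per_decade = 40,
                            range = c(1e-6, 10)) {
  stopifnot(inherits(shear, "shear_field"),
            inherits(field, "fraction_field"))
  vals <- shear$tau[shear$interface]
  if (length(vals) == 0)
    stop("empty interface: no growth-site voxels to count", call. = FALSE)
  h <- field$voxel_size * 1e-6
  fluid_volume <- sum(field$f) * h^3
  n_bins <- max(1L, round(bins_per_decade * log10(range[2] / range[1])))
  breaks <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_bins + 1)
  in_range <- vals >= range[1] & vals <= range[2]
  idx <- findInterval(vals[in_range], breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  dlog <- diff(log10(breaks))
  density <- counts / (dlog * fluid_volume)
  centres <- sqrt(breaks[-1] * breaks[-(n_bins + 1)])
  degenerate <- length(unique(vals)) == 1L
  mom <- if (length(vals) >= 2) distribution_moments(vals) else
    list(mean = mean(vals), sd = 0, skew = 0, kurtosis = 0)
  structure(list(breaks = breaks, centres = centres, counts = counts,
                 density = density,
                 mode = centres[which.max(density)],
                 mean = mom$mean, sd = mom$sd, skew = mom$skew,
                 kurtosis = mom$kurtosis,
                 fluid_volume = fluid_volume, n = length(vals),
                 degenerate = degenerate),
            class = "shear_statistics")
}

#' @export
print.shear_statistics <- function(x, ...) {
  cat(sprintf(
    "shear_statistics: n = %d, mean %.3g Pa, mode %.3g Pa, sd %.3g, skew %.2f, kurtosis %.2f\n",
    x$n, x$mean, x$mode, x$sd, x$skew, x$kurtosis))
  invisible(x)
}

#' Distribution moments
#'
#' Mean, population standard deviation, standardized skewness and
#' \emph{excess} kurtosis (fourth standardized moment minus 3, so a
#' Gaussian scores 0 and a uniform distribution -1.2). For a degenerate
#' (zero-variance) sample, skew and kurtosis are returned as 0 with a
#' `degenerate` flag.
#'
#' @param values numeric vector, `length >= 2`.
#' @return list with `mean`, `sd`, `skew`, `kurtosis`, `degenerate`.
#' @export
distribution_moments <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  d <- values - m
  v <- mean(d^2)
  if (v == 0)
    return(list(mean = m, sd = 0, skew = 0, kurtosis = 0,
                degenerate = TRUE))
  s <- sqrt(v)
  list(mean = m, sd = s,
       skew = mean(d^3) / s^3,
       kurtosis = mean(d^4) / v^2 - 3,
       degenerate = FALSE)
}

#' Growth volume fraction
#'
#' Percent of the initial fluid (channel) volume now occupied by grown
#' cellular matrix: `100 * sum(f_initial - f_now) / sum(f_initial)`,
#' evaluated over the scaffold region (buffers excluded when the fields
#' carry a `scaffold_range` attribute).
#'
#' @param field_now,field_initial [fraction_field()]s on the same grid.
#' @return growth volume fraction in percent.
#' @export
growth_volume_fraction <- function(field_now, field_initial) {
  stopifnot(inherits(field_now, "fraction_field"),
            inherits(field_initial, "fraction_field"))
  if (!identical(dim(field_now$f), dim(field_initial$f)))
    stop("fields are on different grids", call. = FALSE)
  f1 <- scaffold_region(field_now)
  f0 <- scaffold_region(field_initial)
  100 * sum(f0 - f1) / sum(f0)
}

#' Overall growth rate
#'
#' The mean over recorded intervals of the per-interval growth-fraction
#' increment divided by the interval length: an average growth rate in
#' fraction (of initial fluid volume) per second.
#'
#' @param history a `growth_history` from [run_coupled_simulation()], or
#'   a data frame with columns `time_s` and `growth_pct`.
#' @return overall growth rate in 1/s.
#' @export
overall_growth_rate <- function(history) {
  series <- if (inherits(history, "growth_history")) history$series else
    history
  if (nrow(series) < 2)
    stop("need at least 2 time points", call. = FALSE)
  dg <- diff(series$growth_pct / 100)
  dt <- diff(series$time_s)
  mean(dg / dt)
}

#' Flow summary and Darcy permeability
#'
#' Summarizes a converged flow state over the scaffold region (buffers
#' excluded when marked): maximum along-flow velocity component, the
#' fluid-volume-weighted average speed (partially filled voxels weighted
#' by `f`), the maximum pressure variation (max - min over fluid voxels),
#' and the Darcy permeability `k = mu L Q / (A dP)` with `L` the scaffold
#' length along the flow axis, `Q` the volumetric flow rate, `A` the full
#' cross-section and `dP` the area-averaged pressure drop across the
#' scaffold. If the pressure drop vanishes (e.g. an unobstructed duct)
#' the permeability is returned as `NA` with a flag.
#'
#' @param state a `flow_state` from [solve_steady_flow()].
#' @param field the [fraction_field()] the state was solved on.
#' @param bc the [flow_bc()] (defaults to the one in the state).
#' @param props the [fluid_properties()] (defaults to those in the state).
#' @return list of class `flow_summary` with `max_axial_velocity` (m/s),
#'   `mean_speed` (m/s), `max_pressure_variation` (Pa), `permeability`
#'   (m^2, possibly `NA`), `flow_rate` (m^3/s) and
#'   `permeability_defined`.
#' @export
flow_summary <- function(state, field, bc = state$bc, props = state$props) {
  stopifnot(inherits(state, "flow_state"),
            inherits(field, "fraction_field"))
  ax <- axis_index(bc$flow_axis)
  d <- dim(field$f)
  h <- field$voxel_size * 1e-6
  sr <- attr(field, "scaffold_range") %||% c(1L, d[ax])

  # centre-interpolated velocity components
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ucc <- 0.5 * (state$u[1:nx, , , drop = FALSE] +
                state$u[2:(nx + 1), , , drop = FALSE])
  vcc <- 0.5 * (state$v[, 1:ny, , drop = FALSE] +
                state$v[, 2:(ny + 1), , drop = FALSE])
  wcc <- 0.5 * (state$w[, , 1:nz, drop = FALSE] +
                state$w[, , 2:(nz + 1), drop = FALSE])
  axial <- list(ucc, vcc, wcc)[[ax]]
  speed <- sqrt(ucc^2 + vcc^2 + wcc^2)

  slab <- function(arr, r) {
    a <- rep(list(TRUE), 3); a[[ax]] <- r
    do.call(`[`, c(list(arr), a, list(drop = FALSE)))
  }
  reg <- sr[1]:sr[2]
  f_reg <- slab(field$f, reg)
  fluid <- f_reg > 0
  axial_reg <- slab(axial, reg)
  speed_reg <- slab(speed, reg)
  p_reg <- slab(state$p, reg)

  max_axial <- max(axial_reg[fluid])
  mean_speed <- sum(speed_reg * f_reg) / sum(f_reg)
  max_dp <- max(p_reg[fluid]) - min(p_reg[fluid])

  # Darcy permeability across the scaffold
  comp <- state[[c("u", "v", "w")[ax]]]
  q_in <- sum(slab(comp, 1L)) * h^2   # total volumetric rate (conserved)
  area <- prod(d[-ax]) * h^2
  len <- length(reg) * h
  p_up <- slab(state$p, sr[1])
  p_dn <- slab(state$p, sr[2])
  f_up <- slab(field$f, sr[1]); f_dn <- slab(field$f, sr[2])
  dp_darcy <- sum(p_up * f_up) / sum(f_up) - sum(p_dn * f_dn) / sum(f_dn)
  perm_ok <- is.finite(dp_darcy) && abs(dp_darcy) > 1e-300
  k <- if (perm_ok) props$viscosity * len * q_in / (area * dp_darcy) else
    NA_real_
  structure(list(max_axial_velocity = max_axial, mean_speed = mean_speed,
                 max_pressure_variation = max_dp, permeability = k,
                 permeability_defined = perm_ok, flow_rate = q_in,
                 pressure_drop = dp_darcy),
            class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf(
    paste0("flow_summary: max axial velocity %.3g m/s, mean speed %.3g m/s,\n",
           "  max pressure variation %.3g Pa, permeability %s m^2\n"),
    x$max_axial_velocity, x$mean_speed, x$max_pressure_variation,
    if (x$permeability_defined) sprintf("%.3g", x$permeability) else
      "undefined (zero pressure drop)"))
  invisible(x)
}
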