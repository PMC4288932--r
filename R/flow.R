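# Steady incompressible flow through a fraction field: projection method
# with the liquid-fraction momentum sink on a staggered voxel grid.

#' Fluid properties
#'
#' @param density fluid density in kg/m^3 (default 1009, culture medium).
#' @param viscosity dynamic viscosity in kg/(m s) (default 8.4e-4,
#'   culture medium).
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1009, viscosity = 8.4e-4) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(viscosity) || viscosity <= 0) stop("viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Flow boundary conditions
#'
#' A flat (uniform) velocity profile is imposed on the inlet face, a
#' reference pressure on the outlet face, and free-slip no-penetration on
#' the lateral boundaries. All-fluid buffer slabs are added up- and
#' downstream by [assemble_domain()] so the inlet/outlet conditions do not
#' distort the flow inside the scaffold.
#'
#' @param inflow_velocity inlet velocity in m/s (>= 0).
#' @param flow_axis one of "x", "y", "z" (default "z").
#' @param outlet_pressure reference outlet pressure in Pa (default 0).
#' @param buffer_upstream,buffer_downstream buffer lengths in voxels
#'   (default 17 each, about one unit cell at the default grid).
#' @return A list of class `flow_bc`.
#' @export
flow_bc <- function(inflow_velocity, flow_axis = "z", outlet_pressure = 0,
                    buffer_upstream = 17L, buffer_downstream = 17L) {
  if (!is.finite(inflow_velocity) || inflow_velocity < 0)
    stop("inflow_velocity must be >= 0")
  flow_axis <- match.arg(flow_axis, c("x", "y", "z"))
  if (buffer_upstream < 1 || buffer_downstream < 1)
    stop("buffer lengths must be >= 1 voxel")
  structure(list(inflow_velocity = inflow_velocity, flow_axis = flow_axis,
                 outlet_pressure = outlet_pressure,
                 buffer_upstream = as.integer(buffer_upstream),
                 buffer_downstream = as.integer(buffer_downstream)),
            class = "flow_bc")
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))

#' Pad a fraction field with fluid buffer zones
#'
#' Returns the field padded along the flow axis with all-fluid slabs of
#' the configured lengths (regions A and B of the flow system). The
#' scaffold voxels are unchanged; the returned field carries a
#' `scaffold_range` attribute marking the slab range of the original
#' field along the flow axis, used by porosity and summary metrics to
#' exclude the buffers.
#'
#' @param field a [fraction_field()].
#' @param bc a [flow_bc()].
#' @return A padded [fraction_field()].
#' @export
assemble_domain <- function(field, bc) {
  stopifnot(inherits(field, "fraction_field"), inherits(bc, "flow_bc"))
  ax <- axis_index(bc$flow_axis)
  d <- dim(field$f)
  d_up <- d; d_up[ax] <- bc$buffer_upstream
  d_dn <- d; d_dn[ax] <- bc$buffer_downstream
  f_new <- c(array(1, d_up), field$f, array(1, d_dn))
  d_new <- d; d_new[ax] <- d[ax] + bc$buffer_upstream + bc$buffer_downstream
  if (ax == 3L) {
    dim(f_new) <- d_new
  } else {
    # concatenation above is only valid along the last dimension; redo by
    # permuting the axis to the back and inverting afterwards
    perm <- switch(ax, c(2, 3, 1), c(1, 3, 2))
    fp <- aperm(field$f, perm)
    dp <- dim(fp)
    du <- dp; du[3] <- bc$buffer_upstream
    dd <- dp; dd[3] <- bc$buffer_downstream
    stacked <- array(c(array(1, du), fp, array(1, dd)),
                     c(dp[1], dp[2], dp[3] + bc$buffer_upstream +
                         bc$buffer_downstream))
    f_new <- aperm(stacked, order(perm))
  }
  origin <- field$origin
  origin[ax] <- origin[ax] - bc$buffer_upstream * field$voxel_size
  out <- fraction_field(f_new, field$voxel_size, origin)
  attr(out, "scaffold_range") <- c(bc$buffer_upstream + 1L,
                                   bc$buffer_upstream + d[ax])
  attr(out, "flow_axis_index") <- ax
  out
}

# Permute a fraction field so the flow axis is the third dimension.
solver_perm <- function(ax) switch(ax, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))

#' Solve steady flow through a fraction field
#'
#' Marches the projection method in pseudo-time to steady state: an
#' explicit momentum step (first-order upwind convection, central
#' diffusion) multiplied by the face liquid fraction, a pressure Poisson
#' solve by Jacobi-preconditioned conjugate gradients, and a velocity
#' correction that is again multiplied by the liquid fraction so that
#' velocity vanishes identically in solid material. Iterates until the
#' maximum relative velocity change per pseudo-step drops below `tol`.
#'
#' The pseudo-time step is chosen adaptively from the explicit
#' advective-diffusive stability bound,
#' `dt = dt_safety / (6 nu / h^2 + sum(|u|_max) / h)`.
#'
#' A connected-component check is run first; if no open fluid path links
#' inlet to outlet the solve aborts with a blocked-domain error. The
#' Reynolds number (based on the maximum velocity and the lateral domain
#' extent) is reported and a warning is raised if it exceeds 10, outside
#' the laminar creeping-flow regime the model assumes.
#'
#' @param field a [fraction_field()], normally from [assemble_domain()].
#' @param bc a [flow_bc()].
#' @param props a [fluid_properties()].
#' @param tol steady-state criterion: max relative velocity change per
#'   pseudo-step (default 1e-6).
#' @param max_steps pseudo-time step cap.
#' @param cg_rtol relative residual tolerance of the pressure solve
#'   (default 1e-8).
#' @param cg_maxit conjugate-gradient iteration cap per solve.
#' @param init optional previous `flow_state` for a warm start.
#' @param dt_safety safety factor on the stability bound (default 0.9).
#' @param cg_rtol_march looser pressure tolerance used during the
#'   pseudo-time march (the returned state always gets a final projection
#'   at the tight `cg_rtol`).
#' @return A `flow_state`: face-normal velocities `u`, `v`, `w` (m/s,
#'   staggered arrays in the original field orientation), cell-centred
#'   pressure `p` (Pa, relative to the outlet), convergence diagnostics
#'   and the Reynolds number.
#' @export
solve_steady_flow <- function(field, bc, props = fluid_properties(),
                              tol = 1e-6, max_steps = 100000L,
                              cg_rtol = 1e-8, cg_maxit = 5000L,
                              init = NULL, dt_safety = 0.9,
                              cg_rtol_march = 1e-3) {
  stopifnot(inherits(field, "fraction_field"), inherits(bc, "flow_bc"))
  ax <- axis_index(bc$flow_axis)
  perm <- solver_perm(ax)
  fs <- if (ax == 3L) field$f else aperm(field$f, perm)
  dims <- dim(fs)
  h <- field$voxel_size * 1e-6

  init_list <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "flow_state"))
    comp <- c("u", "v", "w")
    init_list <- list(
      u = to_solver_axis(init[[comp[perm[1]]]], perm),
      v = to_solver_axis(init[[comp[perm[2]]]], perm),
      w = to_solver_axis(init[[comp[perm[3]]]], perm),
      p = if (ax == 3L) init$p else aperm(init$p, perm))
    init_list <- lapply(init_list, as.numeric)
  }

  res <- cpp_steady_flow(as.numeric(fs), as.integer(dims), h,
                         props$density, props$viscosity,
                         bc$inflow_velocity, tol, as.integer(max_steps),
                         cg_rtol, as.integer(cg_maxit), init_list,
                         dt_safety, -1.0, cg_rtol_march)
  if (!res$converged)
    warning(sprintf(
      "steady flow did not converge in %d pseudo-steps (rel change %.3g)",
      res$steps, res$rel_change))
  if (res$cg_failures > 0)
    warning(sprintf(
      "pressure CG missed its tolerance in %d of %d pseudo-steps",
      as.integer(res$cg_failures), res$steps))

  u_s <- array(res$u, dims + c(1, 0, 0))
  v_s <- array(res$v, dims + c(0, 1, 0))
  w_s <- array(res$w, dims + c(0, 0, 1))
  p_s <- array(res$p, dims)
  inv <- order(perm)
  vel <- list(NULL, NULL, NULL)
  solver_comps <- list(u_s, v_s, w_s)
  for (q in 1:3) vel[[perm[q]]] <- aperm(solver_comps[[q]], inv)
  p_arr <- aperm(p_s, inv)

  umax <- max(abs(res$u), abs(res$v), abs(res$w))
  lat <- min(dims[1], dims[2]) * h
  re <- props$density * umax * lat / props$viscosity
  if (is.finite(re) && re > 10)
    warning(sprintf(
      "Reynolds number %.2f exceeds 10: outside the laminar creeping-flow regime",
      re))

  structure(list(u = vel[[1]], v = vel[[2]], w = vel[[3]], p = p_arr,
                 converged = res$converged, steps = res$steps,
                 rel_change = res$rel_change, dt = res$dt,
                 cg_iterations = res$cg_iterations,
                 cg_relative_residual = res$cg_relative_residual,
                 reynolds = re, bc = bc, props = props,
                 voxel_size = field$voxel_size, dims = dim(field$f)),
            class = "flow_state")
}

# Bring a face array of the physical component along original axis a into
# solver orientation for component position q (perm[q] = a).
to_solver_axis <- function(arr, perm) {
  if (identical(perm, c(1L, 2L, 3L)) || identical(perm, c(1, 2, 3))) return(arr)
  aperm(arr, perm)
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf(
    "flow_state: %d x %d x %d cells, axis %s, v_in %.3g m/s\n",
    x$dims[1], x$dims[2], x$dims[3], x$bc$flow_axis, x$bc$inflow_velocity))
  cat(sprintf(
    "  %s after %d pseudo-steps (rel change %.2e), Re = %.3g\n",
    if (x$converged) "converged" else "NOT converged", x$steps,
    x$rel_change, x$reynolds))
  invisible(x)
}

#' Explicit momentum step (intermediate velocity)
#'
#' Computes the intermediate velocity `u* = f (u + dt F)`, where `F`
#' collects first-order upwind convection and central-difference diffusion
#' and `f` is the face liquid fraction. Diffusion toward no-slip
#' interfaces (mirror-ghost neighbours) is folded into the update
#' implicitly; this is unconditionally stable for that part of the
#' operator and leaves the steady state unchanged. Low-level building
#' block of [solve_steady_flow()]; operates in solver orientation (flow
#' along the third array dimension).
#'
#' @param state list with staggered face arrays `u`, `v`, `w` (m/s).
#' @param field a [fraction_field()].
#' @param props a [fluid_properties()].
#' @param dt pseudo-time step in s; must satisfy the explicit stability
#'   bound `dt <= 1 / (6 nu / h^2 + sum(|u|_max) / h)`.
#' @param inflow_velocity inlet velocity (m/s) held fixed on the inlet face.
#' @return list of staggered arrays `us`, `vs`, `ws`.
#' @export
advance_momentum <- function(state, field, props, dt, inflow_velocity = 0) {
  dims <- dim(field$f)
  h <- field$voxel_size * 1e-6
  nu <- props$viscosity / props$density
  umax <- max(abs(state$u)) + max(abs(state$v)) + max(abs(state$w))
  dt_lim <- 1 / (6 * nu / h^2 + umax / h)
  if (dt > dt_lim * (1 + 1e-12))
    stop(sprintf("dt = %.3g exceeds the explicit stability limit %.3g",
                 dt, dt_lim), call. = FALSE)
  res <- cpp_momentum(as.numeric(state$u), as.numeric(state$v),
                      as.numeric(state$w), as.numeric(field$f),
                      as.integer(dims), h, dt, props$density,
                      props$viscosity, inflow_velocity)
  list(us = array(res$us, dims + c(1, 0, 0)),
       vs = array(res$vs, dims + c(0, 1, 0)),
       ws = array(res$ws, dims + c(0, 0, 1)))
}

#' Pressure Poisson solve
#'
#' Solves `div(f grad P) = (rho / dt) div(u*)` with Neumann conditions on
#' walls, solid material and the inlet (prescribed flux) and a Dirichlet
#' reference pressure on the outlet face, using Jacobi-preconditioned
#' conjugate gradients on the fluid subdomain. The operator is symmetric
#' positive definite on the outlet-connected fluid component; isolated
#' fluid pockets are pinned to the reference pressure.
#'
#' @param u_star list `us`, `vs`, `ws` from [advance_momentum()].
#' @param field a [fraction_field()].
#' @param props a [fluid_properties()].
#' @param dt pseudo-time step (s).
#' @param p0 optional warm-start pressure array (Pa).
#' @param rtol relative residual tolerance (default 1e-8).
#' @param maxit iteration cap.
#' @return pressure array (Pa) with attributes `iterations`,
#'   `relative_residual` and `converged`.
#' @export
solve_pressure_poisson <- function(u_star, field, props, dt, p0 = NULL,
                                   rtol = 1e-8, maxit = 10000L) {
  dims <- dim(field$f)
  h <- field$voxel_size * 1e-6
  stopifnot(all(is.finite(u_star$us)), all(is.finite(u_star$vs)),
            all(is.finite(u_star$ws)))
  if (is.null(p0)) p0 <- array(0, dims)
  res <- cpp_pressure_solve(as.numeric(u_star$us), as.numeric(u_star$vs),
                            as.numeric(u_star$ws), as.numeric(field$f),
                            as.integer(dims), h, dt, props$density,
                            as.numeric(p0), rtol, as.integer(maxit))
  if (!res$converged)
    stop(sprintf(
      "pressure solver failed to converge: relative residual %.3g after %d iterations",
      res$relative_residual, res$iterations), call. = FALSE)
  p <- array(res$p, dims)
  attr(p, "iterations") <- res$iterations
  attr(p, "relative_residual") <- res$relative_residual
  attr(p, "converged") <- res$converged
  p
}

#' Divergence-removing velocity correction
#'
#' Applies `u = f (u* - (dt / rho) grad P)`: the pressure-gradient
#' correction is multiplied by the face liquid fraction, so the corrected
#' velocity vanishes wherever `f = 0` and is discretely divergence-free in
#' every fluid cell.
#'
#' @inheritParams solve_pressure_poisson
#' @param p pressure array from [solve_pressure_poisson()].
#' @return list of staggered arrays `u`, `v`, `w`.
#' @export
project_velocity <- function(u_star, p, field, props, dt) {
  dims <- dim(field$f)
  h <- field$voxel_size * 1e-6
  res <- cpp_project(as.numeric(u_star$us), as.numeric(u_star$vs),
                     as.numeric(u_star$ws), as.numeric(p),
                     as.numeric(field$f), as.integer(dims), h, dt,
                     props$density)
  list(u = array(res$u, dims + c(1, 0, 0)),
       v = array(res$v, dims + c(0, 1, 0)),
       w = array(res$w, dims + c(0, 0, 1)))
}

#' Discrete divergence of a staggered velocity field
#'
#' @param state list with staggered arrays `u`, `v`, `w` (m/s).
#' @param field a [fraction_field()] (provides the voxel size).
#' @return cell array of `div(u)` in 1/s.
#' @export
velocity_divergence <- function(state, field) {
  dims <- dim(field$f)
  array(cpp_divergence(as.numeric(state$u), as.numeric(state$v),
                       as.numeric(state$w), as.integer(dims),
                       field$voxel_size * 1e-6), dims)
}

#' Mass-conservation check
#'
#' Returns the maximum per-cell divergence of the velocity field and the
#' relative imbalance between inlet and outlet volumetric flow rates.
#'
#' @param state a `flow_state` from [solve_steady_flow()].
#' @param field the [fraction_field()] the state was solved on.
#' @return list with `max_divergence` (1/s), `flow_in`, `flow_out`
#'   (m^3/s) and `imbalance` (relative).
#' @export
check_mass_conservation <- function(state, field) {
  div <- velocity_divergence(state, field)
  h <- field$voxel_size * 1e-6
  ax <- axis_index(state$bc$flow_axis)
  comp <- state[[c("u", "v", "w")[ax]]]
  nface <- dim(comp)[ax]
  take <- function(arr, where) {
    args <- rep(list(TRUE), 3)
    args[[ax]] <- where
    do.call(`[`, c(list(arr), args))
  }
  q_in <- sum(take(comp, 1L)) * h^2
  q_out <- sum(take(comp, nface)) * h^2
  list(max_divergence = max(abs(div)),
       flow_in = q_in, flow_out = q_out,
       imbalance = if (q_in != 0) abs(q_in - q_out) / abs(q_in) else 0)
}
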