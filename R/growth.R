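# Shear-stress evaluation at growth interfaces and the shear-windowed
# linear growth law, coupled back into the flow via the fraction field.

#' Growth-law parameters
#'
#' The growth law is linear in the local shear-stress magnitude:
#' `dG = A * tau * dt` (fraction of voxel volume deposited), with the rate
#' `A * tau` capped at `max_growth_rate`, and zero growth outside the
#' shear window: below `tau_min` the stimulus is insufficient, above
#' `tau_max` cells are washed out. The upper constraint can be disabled
#' (`enforce_max_constraint = FALSE`) to quantify the wash-out effect.
#'
#' Defaults are the model's standard values: `A = 1.5e-4` per (Pa s),
#' window 0.05--56 mPa, maximum rate 1.5e-5 per s.
#'
#' @param growth_factor linear growth factor A in 1/(Pa s).
#' @param tau_min lower (critical) shear threshold in Pa.
#' @param tau_max upper shear threshold in Pa.
#' @param max_growth_rate cap on `A * tau` in 1/s.
#' @param enforce_max_constraint apply the upper window cutoff?
#' @param macro_dt growth macro time step in s (default 3600; the flow is
#'   re-solved to steady state every macro step).
#' @return A list of class `growth_parameters`.
#' @export
growth_parameters <- function(growth_factor = 1.5e-4, tau_min = 5e-5,
                              tau_max = 5.6e-2, max_growth_rate = 1.5e-5,
                              enforce_max_constraint = TRUE,
                              macro_dt = 3600) {
  if (!(tau_min > 0 && tau_max > tau_min))
    stop("need 0 < tau_min < tau_max", call. = FALSE)
  if (growth_factor <= 0) stop("growth_factor must be > 0", call. = FALSE)
  structure(list(growth_factor = growth_factor, tau_min = tau_min,
                 tau_max = tau_max, max_growth_rate = max_growth_rate,
                 enforce_max_constraint = isTRUE(enforce_max_constraint),
                 macro_dt = macro_dt),
            class = "growth_parameters")
}

#' Local shear-stress field
#'
#' Computes the shear-stress tensor components and magnitude at every
#' fluid cell centre from the converged velocity field:
#' `tau_x = mu (du/dy + dv/dx)`, `tau_y = mu (dv/dz + dw/dy)`,
#' `tau_z = mu (dw/dx + du/dz)`, and the magnitude
#' `tau = sqrt(tau_x^2 + tau_y^2 + tau_z^2)`. Velocity gradients are
#' evaluated by linear differencing of the face velocities interpolated
#' to cell centres; where a neighbouring cell is fully solid, a one-sided
#' half-cell difference toward the no-slip interface is used, so the shear
#' is sampled on the fluid side of the growth interface.
#'
#' @param state a `flow_state` from [solve_steady_flow()].
#' @param field the [fraction_field()] the state was solved on.
#' @param viscosity dynamic viscosity in kg/(m s); defaults to the value
#'   stored in the state.
#' @return A list of class `shear_field` with cell arrays `tx`, `ty`,
#'   `tz`, `tau` (Pa) and the logical `interface` mask of growth sites.
#' @export
compute_shear_field <- function(state, field,
                                viscosity = state$props$viscosity) {
  stopifnot(inherits(field, "fraction_field"))
  dims <- dim(field$f)
  res <- cpp_shear(as.numeric(state$u), as.numeric(state$v),
                   as.numeric(state$w), as.numeric(field$f),
                   as.integer(dims), field$voxel_size * 1e-6, viscosity)
  structure(list(tx = array(res$tx, dims), ty = array(res$ty, dims),
                 tz = array(res$tz, dims), tau = array(res$tau, dims),
                 interface = identify_growth_sites(field),
                 viscosity = viscosity),
            class = "shear_field")
}

#' @export
print.shear_field <- function(x, ...) {
  iv <- x$tau[x$interface]
  cat(sprintf(
    "shear_field: %d growth-site voxels, interface tau %.3g .. %.3g Pa (mean %.3g)\n",
    sum(x$interface), if (length(iv)) min(iv) else NA,
    if (length(iv)) max(iv) else NA, if (length(iv)) mean(iv) else NA))
  invisible(x)
}

#' Identify growth sites
#'
#' A voxel is a growth site iff it contains some fluid (`f > 0`) and at
#' least one of its six face neighbours is fully solid (`f = 0`: strut
#' material or completely filled matrix). The growth front therefore
#' advances onto a voxel's fluid neighbours only once that voxel has
#' filled completely, which makes the deposited volume independent of
#' the growth macro-step (a front recruited by any partial fill would
#' instead advance one voxel per step no matter how small the step,
#' leaving the model without a time-step-convergent limit). Partially
#' filled voxels remain sites themselves until they close. Voxels in the
#' all-fluid buffer slabs (outside the `scaffold_range` attribute, when
#' present) are never growth sites: the buffers are kept fully liquid.
#'
#' @param field a [fraction_field()].
#' @return logical array, `TRUE` at growth sites.
#' @export
identify_growth_sites <- function(field) {
  stopifnot(inherits(field, "fraction_field"))
  f <- field$f
  d <- dim(f)
  # minimum f over the six face neighbours; outside the domain counts as
  # fluid (f = 1) so domain boundaries contribute no material neighbours
  nb_min_axis <- function(f, ax) {
    n <- d[ax]
    up <- array(1, d); dn <- array(1, d)
    if (n > 1) {
      slab <- function(r) {
        a <- rep(list(TRUE), 3); a[[ax]] <- r
        do.call(`[`, c(list(f), a, list(drop = FALSE)))
      }
      a <- rep(list(TRUE), 3); a[[ax]] <- 1:(n - 1)
      up <- do.call(`[<-`, c(list(up), a, list(slab(2:n))))
      a[[ax]] <- 2:n
      dn <- do.call(`[<-`, c(list(dn), a, list(slab(1:(n - 1)))))
    }
    pmin(up, dn)
  }
  nb_min <- pmin(nb_min_axis(f, 1), nb_min_axis(f, 2), nb_min_axis(f, 3))
  sites <- (f > 0) & (nb_min <= 0)
  sr <- attr(field, "scaffold_range")
  if (!is.null(sr)) {
    ax <- attr(field, "flow_axis_index") %||% 3L
    keep <- array(FALSE, d)
    args <- rep(list(TRUE), 3); args[[ax]] <- sr[1]:sr[2]
    keep <- do.call(`[<-`, c(list(keep), args, list(TRUE)))
    sites <- sites & keep
  }
  sites
}

#' One growth macro-step
#'
#' Applies the windowed linear growth law at every growth site: the
#' deposited fraction is `dG = min(A * tau, max_growth_rate) * dt`, zero
#' if `tau < tau_min`, and zero if `tau > tau_max` while the upper
#' constraint is enforced. The fluid fraction is reduced by `dG` and
#' clamped at 0 (excess deposition in a nearly full voxel is discarded);
#' growth never reverses. Non-site voxels are unchanged.
#'
#' @param field a [fraction_field()].
#' @param shear a `shear_field` from [compute_shear_field()].
#' @param params a [growth_parameters()].
#' @param dt macro time step in s (>= 0).
#' @return The updated [fraction_field()]; attribute `deposited` holds the
#'   total fraction volume actually deposited (voxel units).
#' @export
growth_step <- function(field, shear, params, dt) {
  stopifnot(inherits(field, "fraction_field"),
            inherits(shear, "shear_field"),
            inherits(params, "growth_parameters"))
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0", call. = FALSE)
  f <- field$f
  sites <- shear$interface
  tau <- shear$tau
  rate <- pmin(params$growth_factor * tau, params$max_growth_rate)
  rate[tau < params$tau_min] <- 0
  if (params$enforce_max_constraint) rate[tau > params$tau_max] <- 0
  dG <- rate * dt
  dG[!sites] <- 0
  f_new <- pmax(f - dG, 0)  # f first: pmax keeps dim from its first arg
  out <- field
  out$f <- f_new
  attr(out, "deposited") <- sum(f - f_new)
  out
}

#' Run the coupled flow-growth simulation
#'
#' Operator-splitting loop over growth macro-steps: the flow is solved to
#' steady state on the current fraction field (warm-started from the
#' previous solution), the local shear field is evaluated, the growth law
#' is applied over one macro step, and the loop repeats until the total
#' simulated time is reached. The quasi-steady coupling is justified by
#' the separation of time scales: the flow relaxes in milliseconds while
#' growth acts over hours.
#'
#' Growth statistics (growth volume fraction, interface shear moments and
#' histogram mode) are recorded at every macro step. If growth occludes
#' the last open flow path, the simulation terminates gracefully and the
#' occlusion time is flagged in the result.
#'
#' @param field an assembled [fraction_field()] (see [assemble_domain()]).
#' @param bc a [flow_bc()].
#' @param props a [fluid_properties()].
#' @param params a [growth_parameters()] (`macro_dt` sets the step).
#' @param total_time total simulated time in s (default 120 h).
#' @param snapshot_times times (s) at which to store fraction-field
#'   snapshots (default the four reporting points 16.7, 50, 83.3, 120 h).
#' @param flow_tol,cg_rtol solver tolerances passed to
#'   [solve_steady_flow()].
#' @param verbose print one line per macro step?
#' @return A `growth_history`: data frame `series` (time_s, growth_pct,
#'   interface shear statistics, flow diagnostics), list `snapshots` of
#'   fraction fields, the final `flow_state` and bookkeeping totals.
#' @export
run_coupled_simulation <- function(field, bc, props = fluid_properties(),
                                   params = growth_parameters(),
                                   total_time = 120 * 3600,
                                   snapshot_times = c(16.7, 50, 83.3, 120) * 3600,
                                   flow_tol = 1e-6, cg_rtol = 1e-8,
                                   verbose = FALSE) {
  stopifnot(inherits(field, "fraction_field"))
  f0 <- field
  n_steps <- if (total_time <= 0) 0L else
    as.integer(ceiling(total_time / params$macro_dt - 1e-9))
  state <- NULL
  occluded_at <- NA_real_
  deposited_total <- 0
  rows <- vector("list", n_steps + 1L)
  snapshots <- list()
  record <- function(t_now, state, shear) {
    iv <- shear$tau[shear$interface]
    mom <- if (length(iv) >= 2) distribution_moments(iv) else
      list(mean = NA_real_, sd = NA_real_, skew = NA_real_,
           kurtosis = NA_real_)
    hist <- if (length(iv) >= 1)
      shear_histogram(shear, field) else NULL
    data.frame(
      time_s = t_now,
      growth_pct = growth_volume_fraction(field, f0),
      shear_mean = mom$mean, shear_sd = mom$sd,
      shear_skew = mom$skew, shear_kurtosis = mom$kurtosis,
      shear_mode = if (!is.null(hist)) hist$mode else NA_real_,
      n_interface = sum(shear$interface),
      max_velocity = max(abs(state$u), abs(state$v), abs(state$w)),
      max_dp = {
        fs <- flow_summary(state, field, bc = bc, props = props)
        fs$max_pressure_variation
      })
  }

  t_now <- 0
  solve_ok <- TRUE
  state <- solve_steady_flow(field, bc, props, tol = flow_tol,
                             cg_rtol = cg_rtol)
  shear <- compute_shear_field(state, field)
  rows[[1]] <- record(t_now, state, shear)
  want_snapshot <- function(t_now)
    length(snapshot_times) > 0 &&
      any(abs(snapshot_times - t_now) < params$macro_dt / 2)
  if (want_snapshot(0)) snapshots[["0"]] <- field

  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      dt_s <- min(params$macro_dt, total_time - t_now)
      field_new <- growth_step(field, shear, params, dt_s)
      deposited_total <- deposited_total + attr(field_new, "deposited")
      field <- field_new
      t_now <- t_now + dt_s
      state <- tryCatch(
        solve_steady_flow(field, bc, props, tol = flow_tol,
                          cg_rtol = cg_rtol, init = state),
        error = function(e) {
          if (grepl("blocked domain", conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(state)) {
        occluded_at <- t_now
        warning(sprintf("flow path occluded at t = %.3g h; stopping growth",
                        t_now / 3600))
        rows <- rows[seq_len(s)]
        break
      }
      shear <- compute_shear_field(state, field)
      rows[[s + 1L]] <- record(t_now, state, shear)
      if (want_snapshot(t_now))
        snapshots[[sprintf("%.6g", t_now)]] <- field
      if (verbose)
        message(sprintf(
          "t = %6.1f h  growth %6.3f%%  mean tau %.3g Pa  (%d flow steps)",
          t_now / 3600, rows[[s + 1L]]$growth_pct, rows[[s + 1L]]$shear_mean,
          state$steps))
    }
  }
  series <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(series = series, snapshots = snapshots,
                 final_field = field, initial_field = f0,
                 final_state = state, occluded_at = occluded_at,
                 deposited_total = deposited_total,
                 params = params, bc = bc, props = props,
                 total_time = total_time),
            class = "growth_history")
}

#' @export
print.growth_history <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf(
    "growth_history: %d time points over %.1f h, final growth %.3f%%\n",
    n, max(x$series$time_s) / 3600, x$series$growth_pct[n]))
  if (!is.na(x$occluded_at))
    cat(sprintf("  flow occluded at %.1f h\n", x$occluded_at / 3600))
  invisible(x)
}
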