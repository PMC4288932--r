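# Simulation configuration: a flat, human-readable key-value file (YAML)
# that round-trips losslessly, plus the full build -> flow -> grow ->
# stats pipeline.

#' Simulation configuration
#'
#' Collects every knob of the pipeline with the model's standard values
#' as defaults. Units: um for geometry, m/s for velocities, Pa for shear
#' thresholds, SI elsewhere.
#'
#' @param n_cells unit cells per axis (length 3 or scalar).
#' @param unit_cell_size_um cubic unit-cell side (um).
#' @param randomize_amplitude vertex perturbation as fraction of the
#'   unit-cell side (0 = regular, 0.3 = the 30\% randomized design).
#' @param seed global seed; drives the lattice randomization (the solver
#'   itself is deterministic).
#' @param voxel_size_um voxel edge (um).
#' @param layer_interval_um slicing interval (um).
#' @param kernel_radius_um sphere kernel radius (um), or `NA` to
#'   calibrate it from `target_porosity`.
#' @param target_porosity porosity target used when `kernel_radius_um`
#'   is `NA`.
#' @param porosity_tolerance calibration tolerance.
#' @param density,viscosity fluid properties (kg/m^3, kg/(m s)).
#' @param inflow_velocity inlet velocity (m/s).
#' @param flow_axis "x", "y" or "z".
#' @param buffer_upstream,buffer_downstream buffer lengths (voxels).
#' @param growth_factor,tau_min,tau_max,max_growth_rate,enforce_max_constraint
#'   growth-law parameters, see [growth_parameters()].
#' @param macro_dt_s growth macro step (s).
#' @param total_hours total simulated growth time (h); 0 runs the flow
#'   and statistics only.
#' @param flow_tol steady-state tolerance of the flow solver.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = c(3, 3, 3),
                              unit_cell_size_um = 600,
                              randomize_amplitude = 0,
                              seed = 1L,
                              voxel_size_um = 36,
                              layer_interval_um = 50,
                              kernel_radius_um = NA_real_,
                              target_porosity = 0.675,
                              porosity_tolerance = 0.005,
                              density = 1009,
                              viscosity = 8.4e-4,
                              inflow_velocity = 2e-5,
                              flow_axis = "z",
                              buffer_upstream = 17L,
                              buffer_downstream = 17L,
                              growth_factor = 1.5e-4,
                              tau_min = 5e-5,
                              tau_max = 5.6e-2,
                              max_growth_rate = 1.5e-5,
                              enforce_max_constraint = TRUE,
                              macro_dt_s = 3600,
                              total_hours = 120,
                              flow_tol = 1e-6) {
  cfg <- list(
    n_cells = rep_len(as.integer(n_cells), 3),
    unit_cell_size_um = as.numeric(unit_cell_size_um),
    randomize_amplitude = as.numeric(randomize_amplitude),
    seed = as.integer(seed),
    voxel_size_um = as.numeric(voxel_size_um),
    layer_interval_um = as.numeric(layer_interval_um),
    kernel_radius_um = as.numeric(kernel_radius_um),
    target_porosity = as.numeric(target_porosity),
    porosity_tolerance = as.numeric(porosity_tolerance),
    density = as.numeric(density),
    viscosity = as.numeric(viscosity),
    inflow_velocity = as.numeric(inflow_velocity),
    flow_axis = match.arg(flow_axis, c("x", "y", "z")),
    buffer_upstream = as.integer(buffer_upstream),
    buffer_downstream = as.integer(buffer_downstream),
    growth_factor = as.numeric(growth_factor),
    tau_min = as.numeric(tau_min),
    tau_max = as.numeric(tau_max),
    max_growth_rate = as.numeric(max_growth_rate),
    enforce_max_constraint = isTRUE(enforce_max_constraint),
    macro_dt_s = as.numeric(macro_dt_s),
    total_hours = as.numeric(total_hours),
    flow_tol = as.numeric(flow_tol))
  class(cfg) <- "simulation_config"
  cfg
}

#' Write / read a simulation configuration
#'
#' YAML key-value serialization; `read_config(write_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a `simulation_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(simulation_config, raw)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Build the scaffold geometry described by a configuration
#'
#' Lattice construction (with optional seeded randomization), slicing,
#' kernel-radius calibration (when no explicit radius is given) and
#' voxelization.
#'
#' @param config a [simulation_config()].
#' @return A [fraction_field()] (scaffold only, no buffers), with the
#'   lattice and the kernel radius attached as attributes.
#' @export
build_scaffold <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lat <- build_regular_lattice(config$n_cells, config$unit_cell_size_um)
  if (config$randomize_amplitude > 0)
    lat <- randomize_lattice(lat, config$randomize_amplitude, config$seed)
  if (is.na(config$kernel_radius_um)) {
    r <- calibrate_kernel_radius(lat, config$target_porosity,
                                 config$porosity_tolerance,
                                 config$voxel_size_um,
                                 config$layer_interval_um)
    field <- attr(r, "field")
    radius <- as.numeric(r)
  } else {
    mp <- slice_lattice(lat, config$layer_interval_um)
    field <- voxelize_spherical(mp, config$voxel_size_um,
                                config$kernel_radius_um,
                                lat$bounding_box)
    radius <- config$kernel_radius_um
  }
  attr(field, "lattice") <- lat
  attr(field, "kernel_radius_um") <- radius
  field
}

#' Run the full simulation pipeline
#'
#' Executes build -> flow -> grow -> stats for one configuration and
#' writes all artifacts into `outdir`: the scaffold volume (raw + header),
#' a VTK snapshot of the initial converged flow, the growth-history
#' container, `growth.csv`, `shear_stats.csv`, `flow_summary.csv`, the
#' resolved configuration (`config.yml`, with an md5 content hash in
#' `run.log`) and a structured log. Identical configuration and seed give
#' identical outputs. On failure, partial artifacts are kept and a
#' `FAILED` marker file records the error.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @param verbose print progress?
#' @return Invisibly, a list with the main results (`field`, `state`,
#'   `history`, `summary`, paths).
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) writeLines("pipeline failed; see run.log",
                        file.path(outdir, "FAILED"))
  })
  cat("", file = logf)
  result <- list()
  t0 <- Sys.time()

  cfg_path <- file.path(outdir, "config.yml")
  write_config(config, cfg_path)
  logline("config written: %s (md5 %s)", cfg_path,
          unname(tools::md5sum(cfg_path)))

  # build
  field <- build_scaffold(config)
  logline("scaffold: %s voxels, porosity %.4f, kernel radius %.2f um",
          paste(dim(field$f), collapse = "x"), compute_porosity(field),
          attr(field, "kernel_radius_um"))
  write_fraction_field(field, file.path(outdir, "scaffold.raw"))

  # flow
  bc <- flow_bc(config$inflow_velocity, config$flow_axis,
                buffer_upstream = config$buffer_upstream,
                buffer_downstream = config$buffer_downstream)
  props <- fluid_properties(config$density, config$viscosity)
  domain <- assemble_domain(field, bc)
  state <- solve_steady_flow(domain, bc, props, tol = config$flow_tol)
  logline("flow: converged=%s in %d pseudo-steps, Re=%.3g",
          state$converged, state$steps, state$reynolds)
  write_vtk_structured(state, domain, file.path(outdir, "flow_initial.vtk"))
  summ <- flow_summary(state, domain, bc, props)
  write.csv(data.frame(
    max_axial_velocity_mps = summ$max_axial_velocity,
    mean_speed_mps = summ$mean_speed,
    max_pressure_variation_pa = summ$max_pressure_variation,
    permeability_m2 = summ$permeability,
    flow_rate_m3ps = summ$flow_rate),
    file.path(outdir, "flow_summary.csv"), row.names = FALSE)

  params <- growth_parameters(config$growth_factor, config$tau_min,
                              config$tau_max, config$max_growth_rate,
                              config$enforce_max_constraint,
                              config$macro_dt_s)
  history <- run_coupled_simulation(
    domain, bc, props, params, total_time = config$total_hours * 3600,
    flow_tol = config$flow_tol, verbose = verbose)
  logline("growth: %d macro steps, final growth %.4f%%",
          nrow(history$series) - 1L,
          history$series$growth_pct[nrow(history$series)])
  write_growth_history(history, file.path(outdir, "history"))
  write.csv(history$series[, c("time_s", "growth_pct")],
            file.path(outdir, "growth.csv"), row.names = FALSE)
  write.csv(data.frame(
    time_s = history$series$time_s,
    inflow_velocity_mps = config$inflow_velocity,
    mean_pa = history$series$shear_mean,
    mode_pa = history$series$shear_mode,
    sd_pa = history$series$shear_sd,
    skew = history$series$shear_skew,
    kurtosis = history$series$shear_kurtosis),
    file.path(outdir, "shear_stats.csv"), row.names = FALSE)

  logline("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ok <- TRUE
  invisible(list(field = field, state = state, history = history,
                 summary = summ, outdir = outdir))
}
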