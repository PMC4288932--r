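# Volume, snapshot and table I/O: raw float32 volumes with text sidecar
# headers, multi-page TIFF stacks, legacy VTK structured-points snapshots
# and the growth-history directory container.

#' Write a fraction field as a raw float32 volume
#'
#' Writes `<path>` as a little-endian float32 volume in column-major
#' (x fastest) order, plus a plain-text sidecar header `<path>.hdr` with
#' the dimensions, voxel size (um) and origin (um).
#'
#' @param field a [fraction_field()].
#' @param path output file path (conventionally `.raw`).
#' @return `path`, invisibly.
#' @export
write_fraction_field <- function(field, path) {
  stopifnot(inherits(field, "fraction_field"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(field$f), con, size = 4, endian = "little")
  hdr <- c(sprintf("dims %d %d %d", dim(field$f)[1], dim(field$f)[2],
                   dim(field$f)[3]),
           sprintf("voxel_size_um %.10g", field$voxel_size),
           sprintf("origin_um %.10g %.10g %.10g", field$origin[1],
                   field$origin[2], field$origin[3]),
           "dtype float32_le")
  sr <- attr(field, "scaffold_range")
  if (!is.null(sr))
    hdr <- c(hdr, sprintf("scaffold_range %d %d", sr[1], sr[2]),
             sprintf("flow_axis_index %d",
                     attr(field, "flow_axis_index") %||% 3L))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read a fraction field written by [write_fraction_field()]
#'
#' @param path path to the raw volume (`<path>.hdr` must exist).
#' @return A [fraction_field()].
#' @export
read_fraction_field <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  get_field <- function(key) {
    line <- grep(paste0("^", key, " "), hdr, value = TRUE)
    if (length(line) != 1) stop("malformed header: missing ", key)
    strsplit(sub(paste0("^", key, " "), "", line), " ")[[1]]
  }
  dims <- as.integer(get_field("dims"))
  voxel <- as.numeric(get_field("voxel_size_um"))
  origin <- as.numeric(get_field("origin_um"))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(dims), size = 4,
                  endian = "little")
  fld <- fraction_field(array(pmin(1, pmax(0, vals)), dims), voxel, origin)
  if (any(grepl("^scaffold_range ", hdr))) {
    attr(fld, "scaffold_range") <- as.integer(get_field("scaffold_range"))
    attr(fld, "flow_axis_index") <- as.integer(get_field("flow_axis_index"))
  }
  fld
}

#' Export a fraction field as a multi-page TIFF stack
#'
#' One 8-bit page per z-slice: 0 = solid, 255 = fluid (intermediate
#' fractions are scaled linearly). Requires the `tiff` package.
#'
#' @param field a [fraction_field()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  stopifnot(inherits(field, "fraction_field"))
  pages <- lapply(seq_len(dim(field$f)[3]), function(k)
    t(field$f[, , k]))  # row-major pages
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Write a flow snapshot as legacy VTK structured points
#'
#' ASCII legacy VTK file with the fraction field, pressure and the
#' centre-interpolated velocity vector as point data on the voxel grid,
#' readable by ParaView and friends.
#'
#' @param state a `flow_state` (or `NULL` to write geometry only).
#' @param field a [fraction_field()].
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(state, field, path) {
  stopifnot(inherits(field, "fraction_field"))
  d <- dim(field$f)
  h <- field$voxel_size
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "perfusim snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.10g %.10g %.10g", field$origin[1],
                       field$origin[2], field$origin[3]),
               sprintf("SPACING %.10g %.10g %.10g", h, h, h),
               sprintf("POINT_DATA %d", n),
               "SCALARS fluid_fraction float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format_chunks(field$f), con)
  if (!is.null(state)) {
    writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
    writeLines(format_chunks(state$p), con)
    nx <- d[1]; ny <- d[2]; nz <- d[3]
    ucc <- 0.5 * (state$u[1:nx, , , drop = FALSE] +
                  state$u[2:(nx + 1), , , drop = FALSE])
    vcc <- 0.5 * (state$v[, 1:ny, , drop = FALSE] +
                  state$v[, 2:(ny + 1), , drop = FALSE])
    wcc <- 0.5 * (state$w[, , 1:nz, drop = FALSE] +
                  state$w[, , 2:(nz + 1), drop = FALSE])
    writeLines("VECTORS velocity float", con)
    vec <- rbind(as.numeric(ucc), as.numeric(vcc), as.numeric(wcc))
    writeLines(paste(format(vec[1, ], digits = 7, scientific = TRUE),
                     format(vec[2, ], digits = 7, scientific = TRUE),
                     format(vec[3, ], digits = 7, scientific = TRUE)), con)
  }
  invisible(path)
}

format_chunks <- function(arr, per_line = 9) {
  vals <- format(as.numeric(arr), digits = 7, scientific = TRUE,
                 trim = TRUE)
  idx <- seq_along(vals)
  as.character(tapply(vals, (idx - 1) %/% per_line, paste, collapse = " "))
}

#' Save a growth history as a directory container
#'
#' Writes `series.csv` (the per-macro-step time series), `meta.yml`
#' (parameters, totals, occlusion flag) and, when snapshots were
#' recorded, one raw float32 volume per snapshot under `snapshots/`.
#'
#' @param history a `growth_history` from [run_coupled_simulation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_growth_history <- function(history, dir) {
  stopifnot(inherits(history, "growth_history"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(history$series, file.path(dir, "series.csv"),
            row.names = FALSE)
  meta <- list(
    total_time_s = history$total_time,
    macro_dt_s = history$params$macro_dt,
    occluded_at_s = if (is.na(history$occluded_at)) "none" else
      history$occluded_at,
    deposited_total_voxels = history$deposited_total,
    growth = unclass(history$params),
    inflow_velocity = history$bc$inflow_velocity,
    flow_axis = history$bc$flow_axis,
    density = history$props$density,
    viscosity = history$props$viscosity)
  yaml::write_yaml(meta, file.path(dir, "meta.yml"))
  if (length(history$snapshots)) {
    sdir <- file.path(dir, "snapshots")
    dir.create(sdir, showWarnings = FALSE)
    for (nm in names(history$snapshots))
      write_fraction_field(history$snapshots[[nm]],
                           file.path(sdir, paste0("t_", nm, "s.raw")))
  }
  invisible(dir)
}
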