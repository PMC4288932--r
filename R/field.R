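# The fraction field: the shared geometry/growth state of the model.

#' Fluid fraction field
#'
#' A `fraction_field` is a 3D voxel array of fluid fraction
#' \eqn{f \in [0,1]}: `f = 1` is pure fluid (open pore), `f = 0` is solid
#' strut material, and `0 < f < 1` is partially grown cellular matrix at a
#' surface. It carries the physical voxel size (um) and the coordinate of
#' the domain corner (um).
#'
#' @param f numeric 3D array with values in `[0, 1]`.
#' @param voxel_size voxel edge length in um.
#' @param origin numeric length-3, position of the lower domain corner (um).
#' @return An object of class `fraction_field`.
#' @export
fraction_field <- function(f, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(f)) != 3) stop("f must be a 3D array", call. = FALSE)
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0", call. = FALSE)
  rng <- range(f)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    stop("f must lie in [0, 1]", call. = FALSE)
  structure(list(f = f, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "fraction_field")
}

#' @export
print.fraction_field <- function(x, ...) {
  d <- dim(x$f)
  cat(sprintf("fraction_field: %d x %d x %d voxels @ %.1f um, porosity %.3f\n",
              d[1], d[2], d[3], x$voxel_size, mean(x$f)))
  sr <- attr(x, "scaffold_range")
  if (!is.null(sr))
    cat(sprintf("  scaffold slabs %d..%d along axis %d (buffers elsewhere)\n",
                sr[1], sr[2], attr(x, "flow_axis_index") %||% 3L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelize melt points with a spherical kernel
#'
#' Emulates the final stage of the virtual selective-laser-melting build:
#' every voxel whose centre lies within `kernel_radius` of any melt point
#' becomes solid (`f = 0`, the strut phase); all other voxels are fluid
#' (`f = 1`, the void phase). With melt points spaced no further apart than
#' the kernel radius, the union of spheres forms continuous struts.
#'
#' @param points a `melt_point_set` from [slice_lattice()], or an n x 3
#'   matrix of points (um).
#' @param voxel_size voxel edge length in um (default 36, the model grid
#'   size).
#' @param kernel_radius sphere kernel radius in um. A radius below half a
#'   voxel triggers a warning (struts may come out disconnected).
#' @param domain 2 x 3 matrix (rows: lower, upper corner in um) bounding
#'   the voxelized volume. Defaults to the tight bounding box of the
#'   points expanded by the kernel radius.
#' @return A [fraction_field()].
#' @export
voxelize_spherical <- function(points, voxel_size = 36, kernel_radius,
                               domain = NULL) {
  pts <- if (inherits(points, "melt_point_set")) points$points else
    matrix(as.numeric(points), ncol = 3)
  if (!is.finite(kernel_radius) || kernel_radius <= 0)
    stop("kernel_radius must be > 0", call. = FALSE)
  if (kernel_radius < voxel_size / 2)
    warning("kernel_radius < voxel_size/2: struts may be disconnected")
  if (is.null(domain)) {
    if (nrow(pts) == 0) stop("domain required for an empty point set",
                             call. = FALSE)
    lo <- apply(pts, 2, min) - kernel_radius
    hi <- apply(pts, 2, max) + kernel_radius
    domain <- rbind(lo, hi)
  }
  domain <- matrix(as.numeric(domain), nrow = 2)
  dims <- pmax(1L, as.integer(round((domain[2, ] - domain[1, ]) / voxel_size)))
  if (nrow(pts) > 0) {
    inside <- pts[, 1] >= domain[1, 1] & pts[, 1] <= domain[2, 1] &
      pts[, 2] >= domain[1, 2] & pts[, 2] <= domain[2, 2] &
      pts[, 3] >= domain[1, 3] & pts[, 3] <= domain[2, 3]
    if (!all(inside))
      stop("all melt points must lie inside the domain", call. = FALSE)
  }
  f <- cpp_voxelize(pts, dims, domain[1, ], voxel_size, kernel_radius)
  dim(f) <- dims
  fraction_field(f, voxel_size, origin = domain[1, ])
}

#' Overall porosity of a fraction field
#'
#' Returns the fluid volume fraction `sum(f) / n_voxels`. If the field
#' carries a `scaffold_range` attribute (set by [assemble_domain()]), the
#' all-fluid buffer slabs are excluded and the porosity refers to the
#' scaffold region only.
#'
#' @param field a [fraction_field()].
#' @return Porosity in `[0, 1]`.
#' @export
compute_porosity <- function(field) {
  stopifnot(inherits(field, "fraction_field"))
  f <- scaffold_region(field)
  mean(f)
}

# Extract the scaffold region of f (drops buffers if present).
scaffold_region <- function(field) {
  f <- field$f
  sr <- attr(field, "scaffold_range")
  if (is.null(sr)) return(f)
  ax <- attr(field, "flow_axis_index") %||% 3L
  idx <- list(seq_len(dim(f)[1]), seq_len(dim(f)[2]), seq_len(dim(f)[3]))
  idx[[ax]] <- sr[1]:sr[2]
  f[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Calibrate the sphere-kernel radius to a target porosity
#'
#' The AM designs are specified by porosity, not strut radius. This
#' bisects the kernel radius so that the voxelized lattice reaches the
#' requested porosity within `tolerance`. Porosity is monotonically
#' non-increasing in the radius on a fixed lattice and grid, so bisection
#' is exact up to the discrete porosity staircase; the result is
#' deterministic for a fixed lattice, grid and bracket.
#'
#' @param lattice a [new_scaffold_lattice()] object.
#' @param target_porosity desired porosity in `(0, 1)` (the regular design
#'   uses 0.675, the randomized one 0.692).
#' @param tolerance acceptable `|porosity - target|` (default 0.005).
#' @param voxel_size voxel edge length in um.
#' @param layer_interval slicing interval in um passed to [slice_lattice()].
#' @param r_bracket initial radius bracket in um.
#' @param max_iter bisection iteration cap.
#' @return The calibrated radius (um), with attributes `porosity` (the
#'   achieved value) and `field` (the voxelized [fraction_field()]).
#' @export
calibrate_kernel_radius <- function(lattice, target_porosity,
                                    tolerance = 0.005, voxel_size = 36,
                                    layer_interval = 50,
                                    r_bracket = c(voxel_size / 2,
                                                  lattice$unit_cell_size / 2),
                                    max_iter = 40) {
  stopifnot(inherits(lattice, "scaffold_lattice"))
  if (!is.finite(target_porosity) || target_porosity <= 0 ||
      target_porosity >= 1)
    stop("target_porosity must be in (0, 1)", call. = FALSE)
  mp <- slice_lattice(lattice, layer_interval)
  domain <- lattice$bounding_box
  por_at <- function(r) {
    fld <- suppressWarnings(
      voxelize_spherical(mp, voxel_size, r, domain))
    list(p = compute_porosity(fld), field = fld)
  }
  lo <- r_bracket[1]; hi <- r_bracket[2]
  p_lo <- por_at(lo); p_hi <- por_at(hi)
  # porosity decreases with radius: need p(lo) >= target >= p(hi)
  if (p_lo$p < target_porosity - tolerance ||
      p_hi$p > target_porosity + tolerance) {
    stop(sprintf(
      paste0("calibration failure: target porosity %.3f unreachable in ",
             "radius bracket [%.1f, %.1f] um (achieved %.3f .. %.3f)"),
      target_porosity, lo, hi, p_hi$p, p_lo$p), call. = FALSE)
  }
  best <- NULL; best_r <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    pm <- por_at(mid)
    if (is.null(best) ||
        abs(pm$p - target_porosity) < abs(best$p - target_porosity)) {
      best <- pm; best_r <- mid
    }
    if (abs(pm$p - target_porosity) <= tolerance) break
    if (pm$p > target_porosity) lo <- mid else hi <- mid
    if (hi - lo < 1e-3) break
  }
  if (abs(best$p - target_porosity) > tolerance)
    stop(sprintf(
      "calibration failure: best porosity %.4f vs target %.4f (tol %.4f)",
      best$p, target_porosity, tolerance), call. = FALSE)
  structure(best_r, porosity = best$p, field = best$field)
}
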