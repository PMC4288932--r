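# Analytic validation fixtures: exact binary geometries with known flow
# solutions (plane Poiseuille, rectangular duct, Hagen-Poiseuille tube).

#' Build an analytic validation fixture
#'
#' Returns exact binary fraction fields for geometries with known
#' analytic (creeping) flow solutions, used to validate the solver:
#' \describe{
#'   \item{plane_channel}{two solid slabs normal to y spanning the full
#'     domain, leaving a fluid gap of `gap` voxels (plane Poiseuille).}
#'   \item{square_duct}{solid walls of thickness `wall` on all four
#'     lateral sides, a rectangular fluid core along z.}
#'   \item{tube}{a solid block with a cylindrical bore of radius
#'     `radius` voxels along z (Hagen-Poiseuille).}
#'   \item{single_strut}{a solid cylinder of radius `radius` voxels along
#'     `strut_axis` immersed in fluid.}
#'   \item{two_voxel_block}{two adjacent solid voxels at the domain
#'     centre (minimal interface test case).}
#' }
#' Geometry is evaluated at voxel centres; the result is exactly binary.
#'
#' @param name fixture name (see above).
#' @param dims integer vector of length 3, domain size in voxels.
#' @param gap fluid gap in voxels (plane_channel).
#' @param wall wall thickness in voxels (square_duct).
#' @param radius bore/strut radius in voxels (tube, single_strut).
#' @param strut_axis axis of the strut cylinder ("x", "y" or "z").
#' @param voxel_size voxel edge length in um.
#' @return A [fraction_field()].
#' @export
make_fixture <- function(name = c("plane_channel", "square_duct", "tube",
                                  "single_strut", "two_voxel_block"),
                         dims, gap = NULL, wall = 1L, radius = NULL,
                         strut_axis = "z", voxel_size = 36) {
  name <- match.arg(name)
  dims <- rep_len(as.integer(dims), 3)
  if (any(dims < 1)) stop("dims must be >= 1", call. = FALSE)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  f <- array(1, dims)
  ic <- function(n) seq_len(n) - 0.5  # voxel-centre coordinates (voxels)

  if (name == "plane_channel") {
    if (is.null(gap)) stop("plane_channel needs `gap`", call. = FALSE)
    if (gap >= ny) stop("gap must leave room for walls", call. = FALSE)
    j0 <- floor((ny - gap) / 2)
    fluid_rows <- (j0 + 1):(j0 + gap)
    f[, setdiff(seq_len(ny), fluid_rows), ] <- 0
  } else if (name == "square_duct") {
    if (2 * wall >= min(nx, ny))
      stop("walls leave no fluid core", call. = FALSE)
    f[c(seq_len(wall), nx - seq_len(wall) + 1), , ] <- 0
    f[, c(seq_len(wall), ny - seq_len(wall) + 1), ] <- 0
  } else if (name == "tube") {
    if (is.null(radius)) stop("tube needs `radius`", call. = FALSE)
    cx <- nx / 2; cy <- ny / 2
    r2 <- outer((ic(nx) - cx)^2, (ic(ny) - cy)^2, `+`)
    solid <- r2 > radius^2
    f <- array(rep(ifelse(solid, 0, 1), nz), dims)
  } else if (name == "single_strut") {
    if (is.null(radius)) stop("single_strut needs `radius`", call. = FALSE)
    ax <- axis_index(match.arg(strut_axis, c("x", "y", "z")))
    lat <- setdiff(1:3, ax)
    c1 <- dims[lat[1]] / 2; c2 <- dims[lat[2]] / 2
    r2 <- outer((ic(dims[lat[1]]) - c1)^2, (ic(dims[lat[2]]) - c2)^2, `+`)
    inside <- r2 <= radius^2
    # broadcast along the strut axis
    perm <- order(c(lat, ax))
    f <- aperm(array(rep(ifelse(inside, 0, 1), dims[ax]),
                     c(dims[lat], dims[ax])), perm)
  } else if (name == "two_voxel_block") {
    ci <- pmax(1L, dims %/% 2L)
    f[ci[1], ci[2], ci[3]] <- 0
    if (ci[1] + 1 <= nx) f[ci[1] + 1, ci[2], ci[3]] <- 0
  }
  fraction_field(f, voxel_size)
}
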