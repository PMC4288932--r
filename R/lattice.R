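# Octahedral unit-cell lattice construction, randomization and slicing.
# All geometry is in physical micrometres.

#' Scaffold strut lattice
#'
#' A `scaffold_lattice` holds the strut network of a block of cubic unit
#' cells: vertex coordinates (micrometres), edges as index pairs, the unit
#' cell size, the cell counts per axis and the bounding box of the block.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (um).
#' @param edges integer matrix, one row per strut, two vertex indices.
#' @param unit_cell_size cubic unit-cell side length (um).
#' @param n_cells integer vector of length 3, cells per axis.
#' @param bounding_box 2 x 3 matrix, rows = lower and upper corner (um).
#' @return An object of class `scaffold_lattice`.
#' @export
new_scaffold_lattice <- function(vertices, edges, unit_cell_size, n_cells,
                                 bounding_box) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    stopifnot(all(edges >= 1), all(edges <= nrow(vertices)),
              all(edges[, 1] != edges[, 2]))
  }
  structure(
    list(vertices = vertices, edges = edges,
         unit_cell_size = unit_cell_size,
         n_cells = as.integer(n_cells),
         bounding_box = matrix(as.numeric(bounding_box), nrow = 2)),
    class = "scaffold_lattice")
}

#' @export
print.scaffold_lattice <- function(x, ...) {
  cat(sprintf(
    "scaffold_lattice: %d x %d x %d unit cells (%.0f um), %d vertices, %d struts\n",
    x$n_cells[1], x$n_cells[2], x$n_cells[3], x$unit_cell_size,
    nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

# Deduplicate vertex rows within `tol` (um) and remap an edge list.
dedup_vertices <- function(vertices, edges, tol = 1e-6) {
  if (nrow(vertices) == 0) return(list(vertices = vertices, edges = edges))
  key <- apply(round(vertices / tol), 1, paste, collapse = ",")
  first_pos <- match(key, key)   # index of first occurrence for each row
  keep <- !duplicated(key)
  map <- cumsum(keep)[first_pos] # old vertex index -> deduplicated index
  list(vertices = vertices[keep, , drop = FALSE],
       edges = matrix(map[edges], ncol = 2))
}

#' Build a regular octahedral unit-cell lattice
#'
#' Fills an `n_cells` block of cubic unit cells with regular octahedra: the
#' six vertices of each octahedron sit at the face centres of its cubic
#' cell, joined by the twelve octahedron edges. Face-centre vertices shared
#' between adjacent cells are stored once (deduplicated within 1e-6 um).
#' This is the standard octahedral unit cell that tessellates in 3D.
#'
#' @param n_cells integer vector of length 3 (or a scalar, recycled):
#'   number of unit cells along x, y, z. Must be >= 1.
#' @param unit_cell_size side length of the cubic unit cell in um
#'   (default 600, the AM design value).
#' @return A [new_scaffold_lattice()] object with bounding box
#'   `[0, n_cells * unit_cell_size]` per axis.
#' @examples
#' lat <- build_regular_lattice(c(1, 1, 1), 600)
#' nrow(lat$vertices)  # 6
#' nrow(lat$edges)     # 12
#' @export
build_regular_lattice <- function(n_cells, unit_cell_size = 600) {
  n_cells <- rep_len(as.integer(n_cells), 3)
  if (any(n_cells < 1))
    stop("n_cells must be >= 1 in each axis", call. = FALSE)
  if (!is.finite(unit_cell_size) || unit_cell_size <= 0)
    stop("unit_cell_size must be > 0", call. = FALSE)
  uc <- unit_cell_size

  # Octahedron template within the unit cube: 6 face centres.
  # Order: -x, +x, -y, +y, -z, +z faces.
  tmpl <- rbind(
    c(0, .5, .5), c(1, .5, .5),
    c(.5, 0, .5), c(.5, 1, .5),
    c(.5, .5, 0), c(.5, .5, 1))
  # 12 edges: every pair of non-opposite vertices.
  opp <- c(2, 1, 4, 3, 6, 5)
  e_tmpl <- t(combn(6, 2))
  e_tmpl <- e_tmpl[opp[e_tmpl[, 1]] != e_tmpl[, 2], , drop = FALSE]
  stopifnot(nrow(e_tmpl) == 12)

  cells <- as.matrix(expand.grid(x = seq_len(n_cells[1]) - 1,
                                 y = seq_len(n_cells[2]) - 1,
                                 z = seq_len(n_cells[3]) - 1))
  nc <- nrow(cells)
  verts <- matrix(0, nc * 6, 3)
  edges <- matrix(0L, nc * 12, 2)
  for (c_i in seq_len(nc)) {
    off <- cells[c_i, ]
    verts[(c_i - 1) * 6 + 1:6, ] <- (tmpl + rep(off, each = 6)) * uc
    edges[(c_i - 1) * 12 + 1:12, ] <- e_tmpl + (c_i - 1L) * 6L
  }
  dd <- dedup_vertices(verts, edges)
  new_scaffold_lattice(dd$vertices, dd$edges, uc, n_cells,
                       rbind(c(0, 0, 0), n_cells * uc))
}

#' Randomize lattice vertex positions
#'
#' Displaces each vertex coordinate independently per axis by a uniform
#' draw in `[-a * UC, +a * UC]`, where `a = amplitude_fraction` and `UC`
#' is the unit-cell size, while keeping the strut connectivity (edge list)
#' unchanged. Vertices lying on the outer faces of the scaffold block are
#' perturbed only tangentially (displacement components normal to those
#' faces are suppressed) so the block envelope, and hence the inlet and
#' outlet cross-sections, are preserved.
#'
#' The randomization is driven by `seed` alone and is fully reproducible:
#' the same lattice, amplitude and seed give a bit-identical result. The
#' caller's RNG state is left untouched.
#'
#' @param lattice a [new_scaffold_lattice()] object.
#' @param amplitude_fraction perturbation amplitude as a fraction of the
#'   unit-cell side, in `[0, 0.5]` (the AM design uses 0.3, i.e. +/-30%).
#' @param seed integer seed for the pseudo-random perturbation.
#' @return A `scaffold_lattice` with displaced vertices, identical edges.
#' @export
randomize_lattice <- function(lattice, amplitude_fraction, seed = 1L) {
  stopifnot(inherits(lattice, "scaffold_lattice"))
  if (!is.finite(amplitude_fraction) ||
      amplitude_fraction < 0 || amplitude_fraction > 0.5)
    stop("amplitude_fraction must be in [0, 0.5]", call. = FALSE)
  v <- lattice$vertices
  n <- nrow(v)
  if (n == 0 || amplitude_fraction == 0) return(lattice)
  a <- amplitude_fraction * lattice$unit_cell_size

  disp <- local_runif_matrix(n, 3, seed) * 2 * a - a

  # Freeze displacement components normal to the outer envelope.
  bb <- lattice$bounding_box
  tol <- 1e-9 * max(1, abs(bb))
  for (ax in 1:3) {
    on_face <- abs(v[, ax] - bb[1, ax]) < tol | abs(v[, ax] - bb[2, ax]) < tol
    disp[on_face, ax] <- 0
  }
  out <- lattice
  out$vertices <- v + disp
  out
}

# Uniform(0,1) draws from a private RNG stream; global RNG state untouched.
local_runif_matrix <- function(n, m, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  matrix(runif(n * m), n, m)
}

#' Slice a lattice into laser melt points
#'
#' Emulates the slicing stage of selective laser melting: every strut is
#' intersected with the horizontal planes `z = k * layer_interval`, and the
#' intersection points plus both strut endpoints are emitted. Struts lying
#' entirely within a slicing plane (and any segment between consecutive
#' emitted points that is longer than `layer_interval` in 3D, as happens
#' for nearly-horizontal struts of randomized lattices) are additionally
#' subdivided so that consecutive melt points along a strut are no further
#' than `layer_interval` apart; this keeps the subsequent sphere-kernel
#' voxelization continuous along every strut. Duplicate points are merged
#' within `merge_tol`.
#'
#' @param lattice a [new_scaffold_lattice()] object.
#' @param layer_interval slicing interval in um (default 50, the SLM layer
#'   height).
#' @param merge_tol merge tolerance for duplicate points (um).
#' @return A list of class `melt_point_set` with elements `points`
#'   (n x 3 matrix, um) and `layer_interval`.
#' @export
slice_lattice <- function(lattice, layer_interval = 50,
                          merge_tol = layer_interval / 500) {
  stopifnot(inherits(lattice, "scaffold_lattice"))
  if (!is.finite(layer_interval) || layer_interval <= 0)
    stop("layer_interval must be > 0", call. = FALSE)
  v <- lattice$vertices
  e <- lattice$edges
  if (nrow(e) == 0) {
    return(structure(list(points = matrix(numeric(0), 0, 3),
                          layer_interval = layer_interval),
                     class = "melt_point_set"))
  }
  pts_list <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    p0 <- v[e[i, 1], ]
    p1 <- v[e[i, 2], ]
    dz <- p1[3] - p0[3]
    ts <- c(0, 1)
    if (abs(dz) > 1e-12) {
      k0 <- ceiling(min(p0[3], p1[3]) / layer_interval - 1e-12)
      k1 <- floor(max(p0[3], p1[3]) / layer_interval + 1e-12)
      if (k1 >= k0) {
        zs <- (k0:k1) * layer_interval
        ts <- c(ts, (zs - p0[3]) / dz)
      }
    }
    ts <- sort(pmin(pmax(ts, 0), 1))
    # subdivide long 3D gaps (in-plane or nearly-horizontal struts)
    len <- sqrt(sum((p1 - p0)^2))
    if (len > 0) {
      out_ts <- ts[1]
      for (j in seq_along(ts)[-1]) {
        gap <- (ts[j] - ts[j - 1]) * len
        if (gap > layer_interval * (1 + 1e-9)) {
          nseg <- ceiling(gap / layer_interval)
          out_ts <- c(out_ts, ts[j - 1] + (ts[j] - ts[j - 1]) *
                        seq_len(nseg - 1) / nseg)
        }
        out_ts <- c(out_ts, ts[j])
      }
      ts <- out_ts
    }
    pts_list[[i]] <- cbind(p0[1] + ts * (p1[1] - p0[1]),
                           p0[2] + ts * (p1[2] - p0[2]),
                           p0[3] + ts * (p1[3] - p0[3]))
  }
  pts <- do.call(rbind, pts_list)
  key <- apply(round(pts / merge_tol), 1, paste, collapse = ",")
  pts <- pts[!duplicated(key), , drop = FALSE]
  structure(list(points = pts, layer_interval = layer_interval),
            class = "melt_point_set")
}

#' @export
print.melt_point_set <- function(x, ...) {
  cat(sprintf("melt_point_set: %d points, layer interval %.1f um\n",
              nrow(x$points), x$layer_interval))
  invisible(x)
}
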