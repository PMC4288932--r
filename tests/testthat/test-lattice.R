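# Octahedral lattice construction, randomization and slicing.

test_that("regular lattice has face-centre octahedra with shared vertices", {
  lat <- build_regular_lattice(c(1, 1, 1), 600)
  expect_equal(nrow(lat$vertices), 6)
  expect_equal(nrow(lat$edges), 12)
  # brute-force oracle: face centres of the unit cube scaled by 600
  fc <- rbind(c(0, .5, .5), c(1, .5, .5), c(.5, 0, .5),
              c(.5, 1, .5), c(.5, .5, 0), c(.5, .5, 1)) * 600
  perm <- apply(lat$vertices, 1, function(v)
    which(colSums(abs(t(fc) - v)) < 1e-9))
  expect_setequal(perm, 1:6)
  # every edge joins non-opposite vertices: distance 600/sqrt(2)
  el <- sqrt(rowSums((lat$vertices[lat$edges[, 1], ] -
                      lat$vertices[lat$edges[, 2], ])^2))
  expect_equal(el, rep(600 / sqrt(2), 12))
  # all vertices inside the unit cell
  expect_true(all(lat$vertices >= 0 & lat$vertices <= 600))

  lat2 <- build_regular_lattice(c(2, 1, 1), 600)
  expect_equal(nrow(lat2$vertices), 11)  # one shared face-centre vertex
  expect_equal(nrow(lat2$edges), 24)

  expect_error(build_regular_lattice(c(0, 1, 1)), "n_cells")
  expect_error(build_regular_lattice(1, -5), "unit_cell_size")
})

test_that("randomization is bounded, tangential on faces and reproducible", {
  lat <- build_regular_lattice(c(2, 2, 2), 600)
  r1 <- randomize_lattice(lat, 0.3, seed = 42)
  r2 <- randomize_lattice(lat, 0.3, seed = 42)
  expect_identical(r1$vertices, r2$vertices)     # seeded determinism
  expect_identical(r1$edges, lat$edges)          # connectivity maintained
  disp <- abs(r1$vertices - lat$vertices)
  expect_true(all(disp <= 0.3 * 600 + 1e-9))     # +/-30% of the UC side
  expect_false(identical(r1$vertices, lat$vertices))
  r3 <- randomize_lattice(lat, 0.3, seed = 43)
  expect_false(identical(r1$vertices, r3$vertices))

  # amplitude 0 is the identity
  expect_identical(randomize_lattice(lat, 0, seed = 1)$vertices,
                   lat$vertices)

  # envelope vertices keep their on-face coordinates
  bb <- lat$bounding_box
  for (ax in 1:3) {
    on_face <- abs(lat$vertices[, ax] - bb[1, ax]) < 1e-9 |
      abs(lat$vertices[, ax] - bb[2, ax]) < 1e-9
    expect_identical(r1$vertices[on_face, ax], lat$vertices[on_face, ax])
  }
  # ... and interior coordinates really move
  expect_true(any(disp > 1))

  expect_error(randomize_lattice(lat, 0.6), "amplitude")

  # the caller's RNG state is untouched
  set.seed(7); before <- .Random.seed
  invisible(randomize_lattice(lat, 0.3, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("slicing emits endpoints, plane crossings and no long gaps", {
  # single vertical strut: planes every 50 um from 0 to 600 -> 13 points
  lat <- new_scaffold_lattice(rbind(c(0, 0, 0), c(0, 0, 600)),
                              rbind(c(1, 2)), 600, c(1, 1, 1),
                              rbind(c(0, 0, 0), c(600, 600, 600)))
  mp <- slice_lattice(lat, 50)
  expect_equal(nrow(mp$points), 13)
  expect_equal(sort(mp$points[, 3]), seq(0, 600, by = 50))

  # short horizontal strut between planes: endpoints only
  lat2 <- new_scaffold_lattice(rbind(c(0, 0, 25), c(40, 0, 25)),
                               rbind(c(1, 2)), 600, c(1, 1, 1),
                               rbind(c(0, 0, 0), c(600, 600, 600)))
  expect_equal(nrow(slice_lattice(lat2, 50)$points), 2)

  # no edges -> no points (not an error)
  lat3 <- new_scaffold_lattice(matrix(numeric(0), 0, 3),
                               matrix(integer(0), 0, 2), 600, c(1, 1, 1),
                               rbind(c(0, 0, 0), c(600, 600, 600)))
  expect_equal(nrow(slice_lattice(lat3, 50)$points), 0)

  # long in-plane or shallow struts are subdivided: consecutive melt
  # points along any strut are <= one layer interval apart in 3D
  lat4 <- new_scaffold_lattice(rbind(c(0, 0, 300), c(424, 0, 302)),
                               rbind(c(1, 2)), 600, c(1, 1, 1),
                               rbind(c(0, 0, 0), c(600, 600, 600)))
  mp4 <- slice_lattice(lat4, 50)
  pts <- mp4$points[order(mp4$points[, 1]), ]
  gaps <- sqrt(rowSums(diff(pts)^2))
  expect_true(all(gaps <= 50 + 1e-9))

  expect_error(slice_lattice(lat, 0), "layer_interval")
})

test_that("full octahedral lattice slicing covers every strut densely", {
  lat <- build_regular_lattice(c(2, 2, 2), 600)
  mp <- slice_lattice(lat, 50)
  # each of the 96 struts must carry points at most 50 um apart, so the
  # voxelized struts stay continuous
  v <- lat$vertices
  for (e in sample(nrow(lat$edges), 10)) {
    p0 <- v[lat$edges[e, 1], ]; p1 <- v[lat$edges[e, 2], ]
    dir <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    rel <- sweep(mp$points, 2, p0)
    t_on <- as.numeric(rel %*% dir)
    # perpendicular distance via the residual vector (cancellation-safe)
    resid <- rel - outer(t_on, dir)
    perp <- sqrt(rowSums(resid^2))
    on_edge <- perp < 1e-3 & t_on > -1e-6 &
      t_on < sqrt(sum((p1 - p0)^2)) + 1e-6
    ts <- sort(t_on[on_edge])
    expect_gt(length(ts), 2)
    expect_lte(max(diff(ts)), 50 + 1e-9)
  }
})
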