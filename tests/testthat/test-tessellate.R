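test_that("an unjittered 1x4 tube partitions into equal rectangles", {
  sp <- tubeSpec(radius = 5, length = 25, nRings = 1L, nAround = 4L,
                 vertexJitter = 0, seed = 1L)
  g <- tessellateTube(sp)
  areas <- g@cellInfo$areaUm2
  expect_length(areas, 4L)
  expect_equal(areas, rep(2 * pi * 5 * 25 / 4, 4))
  # axis-aligned grid: every junction exactly longitudinal or transverse
  expect_true(all(junctions(g)$angleDeg %in% c(0, 90)))
  expect_true(all(junctions(g)$class %in% c("LCJ", "TCJ")))
})

test_that("junction census matches a brute-force lattice enumeration", {
  sp <- tubeSpec(radius = 6, length = 30, nRings = 6L, nAround = 8L,
                 vertexJitter = 0, seed = 2L)
  g <- tessellateTube(sp)
  # oracle: enumerate unique lattice edges geometrically. Vertices of
  # the brick lattice are all (m * w/2, k * h) present on line k;
  # vertical edges connect equal u across adjacent lines, horizontal
  # edges connect u-neighbours along a line (with wraparound).
  nA <- 8L; nR <- 6L
  w2 <- (2 * pi * 6 / nA) / 2
  edges <- character(0)
  lineMs <- function(k) {
    if (k == 0L) seq(0L, 2L * nA - 2L, 2L)
    else if (k == nR) seq((nR - 1L) %% 2L, 2L * nA - 1L, 2L)
    else 0:(2L * nA - 1L)
  }
  for (row in 0:(nR - 1L)) {
    for (m in seq(row %% 2L, 2L * nA - 1L, 2L)) {
      edges <- c(edges, sprintf("V|%d|%d", row, m))
    }
  }
  for (k in 0:nR) {
    ms <- lineMs(k)
    edges <- c(edges, sprintf("H|%d|%d", k, seq_along(ms)))
  }
  expect_equal(nrow(junctions(g)), length(unique(edges)))
  # and the per-class split: verticals are LCJ, horizontals TCJ
  expect_equal(sum(junctions(g)$class == "LCJ"), nR * nA)
  expect_equal(sum(junctions(g)$class == "TCJ"),
               length(edges) - nR * nA)
})

test_that("tessellation tiles the tube surface exactly, jitter or not", {
  for (seed in c(3L, 4L, 5L)) {
    sp <- tubeSpec(vertexJitter = 0.2, seed = seed)
    g <- tessellateTube(sp)
    expect_equal(sum(g@cellInfo$areaUm2),
                 2 * pi * sp@radius * sp@length, tolerance = 1e-9)
  }
})

test_that("every junction is bounded by one or two cells and is
           non-degenerate", {
  g <- tessellateTube(tubeSpec(seed = 6L))
  j <- junctions(g)
  nBound <- (!is.na(j$cellA)) + (!is.na(j$cellB))
  expect_true(all(nBound %in% 1:2))
  # tube-end transverse junctions have exactly one cell
  expect_true(all(nBound[j$class == "LCJ"] == 2))
  expect_true(all(j$lengthUm > 0))
  # bounding cell ids are valid
  ids <- g@cellInfo$id
  expect_true(all(stats::na.omit(c(j$cellA, j$cellB)) %in% ids))
})

test_that("identical seeds reproduce the tessellation bit for bit", {
  a <- tessellateTube(tubeSpec(seed = 7L))
  b <- tessellateTube(tubeSpec(seed = 7L))
  expect_identical(a@junctions, b@junctions)
  expect_identical(a@polylines3D, b@polylines3D)
  c <- tessellateTube(tubeSpec(seed = 8L))
  expect_false(identical(a@junctions$angleDeg, c@junctions$angleDeg))
})

test_that("cells smaller than 4 voxels are rejected as unresolvable", {
  expect_error(
    tessellateTube(tubeSpec(radius = 1, length = 4, nRings = 8L,
                            nAround = 8L, voxel = c(0.25, 0.25, 0.25))),
    "4 voxels")
})

test_that("a straight tube records a straight medial axis", {
  g <- tessellateTube(tubeSpec(curvature = 0, seed = 9L))
  ax <- medialAxis(g)
  expect_true(all(abs(ax[, 2]) < 1e-12) && all(abs(ax[, 3]) < 1e-12))
  # curved tube: axis arclength preserved, endpoints bent off-axis
  gb <- tessellateTube(tubeSpec(curvature = 0.02, seed = 9L))
  axb <- medialAxis(gb)
  arc <- sum(sqrt(rowSums(diff(axb)^2)))
  expect_equal(arc, 35, tolerance = 1e-3)
  expect_gt(max(abs(axb[, 2])), 1)
})
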