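test_that("signed distance matches the analytic sphere", {
  sph <- meshSphere(radius = 1, subdivisions = 4)
  d <- signedDistance(sph, rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 1)))
  expect_equal(d[1], -1, tolerance = 5e-3)   # centre: one radius inside
  expect_equal(d[2], 1, tolerance = 5e-3)    # outside along x
  expect_lt(abs(d[3]), 5e-3)                 # on the surface
  open <- meshHemisphere(radius = 5, n = 24)
  expect_error(signedDistance(open, rbind(c(0, 0, 0))), "watertight")
})

test_that("solidifyShell produces a watertight shell of the right volume", {
  hemi <- meshHemisphere(radius = 20, n = 64)
  shell <- solidifyShell(hemi, 6, "inward", resolution = 0.4)
  expect_watertight(shell)
  analytic <- 2 / 3 * pi * (20^3 - 14^3)
  expect_equal(meshVolume(shell), analytic, tolerance = 0.03)
  # outer sheet coincides with the input surface
  set.seed(1)
  sp <- sampleSurfacePoints(shell, 500)
  outer <- sp$points[rowSums(sp$points^2) > 17^2 & sp$points[, 3] > 1, , drop = FALSE]
  expect_lt(max(abs(sqrt(rowSums(outer^2)) - 20)), 0.25)
  expect_error(solidifyShell(hemi, 0), "positive")
  expect_error(solidifyShell(hemi, -2), "positive")
})

test_that("boolean subtraction matches the analytic cube oracle", {
  a <- meshBox(c(0, 0, 0), c(10, 10, 10))
  b <- meshBox(c(5, 0, 0), c(15, 10, 10))
  dif <- booleanSubtract(a, b, resolution = 0.1)
  expect_watertight(dif)
  expect_equal(meshVolume(dif), 500, tolerance = 0.005)

  # oracle: classification against the analytic boxes on a regular grid;
  # mismatches must be confined to within one grid cell of either surface
  h <- 0.1
  g <- expand.grid(x = seq(-1, 11, by = 0.83), y = seq(-1, 11, by = 0.79),
                   z = seq(-1, 11, by = 0.87))
  pts <- as.matrix(g)
  inA <- pts[, 1] > 0 & pts[, 1] < 10 & pts[, 2] > 0 & pts[, 2] < 10 &
    pts[, 3] > 0 & pts[, 3] < 10
  inB <- pts[, 1] > 5 & pts[, 1] < 15 & pts[, 2] > 0 & pts[, 2] < 10 &
    pts[, 3] > 0 & pts[, 3] < 10
  expected <- inA & !inB
  # margin: points farther than one cell from the expected boundary
  distToBoundary <- pmin(
    abs(pts[, 1]), abs(pts[, 1] - 5), abs(pts[, 2]), abs(pts[, 2] - 10),
    abs(pts[, 3]), abs(pts[, 3] - 10), abs(pts[, 1] - 10))
  away <- distToBoundary > h
  got <- signedDistance(dif, pts[away, , drop = FALSE]) < 0
  expect_equal(got, expected[away])
})

test_that("boolean edge cases behave by contract", {
  a <- meshBox(c(0, 0, 0), c(10, 10, 10))
  disjoint <- meshBox(c(50, 50, 50), c(60, 60, 60))
  kept <- booleanSubtract(a, disjoint, resolution = 0.15)
  expect_equal(meshVolume(kept), meshVolume(a), tolerance = 0.001)
  nothing <- booleanSubtract(a, a, resolution = 0.15)
  expect_lt(abs(meshVolume(nothing)), 1)
  open <- meshHemisphere(radius = 5, n = 24)
  expect_error(booleanSubtract(a, open), "watertight")
})

test_that("region smoothing moves only interior region vertices", {
  plate <- meshPlate(c(-10, 10), c(-10, 10), z0 = 0, nx = 25, ny = 25)
  v <- meshVertices(plate)
  region <- RegionMask(abs(v[, 1]) < 5 & abs(v[, 2]) < 5)

  # a planar region is a fixed point of umbrella smoothing
  out <- regionSmooth(plate, region, iterations = 20, strength = 0.5)
  expect_equal(meshVertices(out), v, tolerance = 1e-12)

  # iterations = 0 is the identity; negative iterations error
  expect_identical(meshVertices(regionSmooth(plate, region, 0)), v)
  expect_error(regionSmooth(plate, region, -1), ">= 0")

  # noisy patch: height deviation variance strictly decreases inside the
  # smoothed region, and vertices outside the region stay put
  set.seed(42)
  noisy <- v
  noisy[, 3] <- rnorm(nrow(v), 0, 0.1)
  noisyMesh <- TriangleMesh(noisy, meshFaces(plate))
  sm <- regionSmooth(noisyMesh, region, iterations = 10, strength = 0.5)
  inner <- region@flags & abs(noisy[, 1]) < 4 & abs(noisy[, 2]) < 4
  expect_lt(var(meshVertices(sm)[inner, 3]), var(noisy[inner, 3]))
  expect_identical(meshVertices(sm)[!region@flags, ], noisy[!region@flags, ])
})

test_that("densification meets the edge-length target without moving the surface", {
  hemi <- meshHemisphere(radius = 20, n = 32)
  el0 <- noseforge:::edgeLengths(hemi)
  dens <- densifyMesh(hemi, 1)
  el <- noseforge:::edgeLengths(dens)
  expect_gte(mean(el <= 1), 0.95)
  # subdivision is geometry-preserving
  expect_lt(hausdorffDistance(hemi, dens), 1 / 4)

  # halving the target roughly quadruples the face count
  d1 <- densifyMesh(hemi, 2)
  d2 <- densifyMesh(hemi, 1)
  ratio <- nFaces(d2) / nFaces(d1)
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)

  # a target above the largest edge returns the mesh unchanged
  expect_identical(densifyMesh(hemi, max(el0) * 1.01), hemi)
  expect_error(densifyMesh(hemi, 0), "positive")
})

test_that("mesh cleaning merges duplicates and drops degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0) + 1e-9)
  f <- rbind(c(1, 2, 3), c(4, 2, 3), c(2, 2, 3))
  m <- suppressWarnings(TriangleMesh(v, f[1:2, , drop = FALSE]))
  cl <- cleanMesh(m)
  expect_equal(nVertices(cl), 3L)
  expect_equal(nFaces(cl), 1L)  # the duplicate face collapses onto the first
})

test_that("watertightness audit distinguishes open from closed meshes", {
  expect_true(isWatertight(meshBox()))
  expect_true(isWatertight(meshSphere(subdivisions = 2)))
  expect_true(isWatertight(meshCylinder(c(0, 0, 0), c(0, 0, 1), 2, 5)))
  expect_false(isWatertight(meshHemisphere(n = 16)))
  expect_false(isWatertight(meshPlate(nx = 5, ny = 5)))
  expect_equal(boundaryLoops(meshHemisphere(n = 16))$nLoops, 1L)
})
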