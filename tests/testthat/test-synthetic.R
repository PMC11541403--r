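test_that("face generation is deterministic and parameter-faithful", {
  topo <- faceTopology(64, 64)
  a <- generateFace(faceParams(), topo)
  b <- generateFace(faceParams(), topo)
  expect_identical(meshVertices(a$mesh), meshVertices(b$mesh))
  expect_identical(a$noseMask@flags, b$noseMask@flags)

  # a degenerate nose leaves an empty mask
  flat <- generateFace(faceParams(bridgeHeight = 0, tipProjection = 0), topo)
  expect_false(any(flat$noseMask@flags))

  # raising the tip projection by delta raises the tip vertex by about delta
  p0 <- faceParams()
  p1 <- faceParams(tipProjection = p0@tipProjection + 4)
  z0 <- meshVertices(generateFace(p0, topo)$mesh)[, 3]
  z1 <- meshVertices(generateFace(p1, topo)$mesh)[, 3]
  expect_equal(max(z1 - z0), 4, tolerance = 0.1)

  expect_error(generateFace(faceParams(noseWidth = -1)), "positive")
})

test_that("population generation is reproducible and in correspondence", {
  topo <- faceTopology(64, 64)
  p1 <- generatePopulation(12, seed = 99, topology = topo)
  p2 <- generatePopulation(12, seed = 99, topology = topo)
  expect_identical(meshVertices(p1[[7]]), meshVertices(p2[[7]]))
  expect_true(all(vapply(p1, function(m) identical(meshFaces(m), meshFaces(p1[[1]])),
                         logical(1))))
  expect_error(generatePopulation(1, seed = 1), "at least 2")

  # distribution check: sample mean of nose length within 3 SE
  big <- generatePopulation(200, seed = 7, topology = faceTopology(16, 16))
  draws <- attr(big, "params")
  se <- 4 / sqrt(200)
  expect_lt(abs(mean(draws$noseLength) - 50), 3 * se + 0.3)  # + truncation slack
})

test_that("simulated rhinectomy removes the dilated nose and keeps the truth", {
  topo <- faceTopology(64, 64)
  gf <- generateFace(faceParams(), topo)
  # margin 0, no noise: identical to plain erasure
  rh0 <- simulateRhinectomy(gf$mesh, gf$noseMask, margin = 0, noiseSd = 0)
  expect_identical(meshVertices(rh0$fm),
                   meshVertices(eraseRegion(gf$mesh, gf$noseMask)))
  # the removed set always contains the nose mask
  set.seed(2)
  rh <- simulateRhinectomy(gf$mesh, gf$noseMask, margin = 3, noiseSd = 0.1)
  expect_true(all(which(gf$noseMask@flags) %in% rh$removed))
  expect_identical(rh$groundTruth, gf$mesh)
  expect_equal(nVertices(rh$fm), nVertices(gf$mesh) - length(rh$removed))
  expect_error(simulateRhinectomy(gf$mesh, gf$noseMask, margin = -1), ">= 0")
})

test_that("the CT voxelization route reproduces the surface within a voxel", {
  topo <- faceTopology(48, 48)
  gf <- generateFace(faceParams(faceBreadth = 120), topo)
  # restrict to the central face so the test stays light
  v <- meshVertices(gf$mesh)
  keep <- abs(v[, 1]) < 40 & abs(v[, 2]) < 45
  crop <- cleanMesh(eraseRegion(gf$mesh, RegionMask(!keep)))

  spacing <- c(0.46, 0.46, 1)  # CT-like: pixel spacing x slice thickness
  out <- voxelizeCtRoute(crop, spacing)
  expect_gt(nFaces(out), 100)
  # directional Hausdorff within one voxel diagonal, evaluated away from
  # the open rim of the cropped sheet (the extraction deliberately trims
  # the rim band, which would otherwise dominate the coverage direction)
  ctError <- function(input, output) {
    qi <- noseforge:::meshQuery(input)
    qo <- noseforge:::meshQuery(output)
    dOut <- max(noseforge:::cpp_closest(qi, meshVertices(output))$distance)
    vi <- meshVertices(input)
    rim <- vi[boundaryLoops(input)$vertices, , drop = FALSE]
    d2 <- outer(rowSums(vi^2), rowSums(rim^2), "+") - 2 * vi %*% t(rim)
    interior <- sqrt(pmax(apply(d2, 1, min), 0)) > 4
    dIn <- max(noseforge:::cpp_closest(qo, vi[interior, , drop = FALSE])$distance)
    max(dOut, dIn)
  }
  expect_lt(ctError(crop, out), sqrt(sum(spacing^2)))

  # finer spacing gives a monotonically smaller reconstruction error
  errs <- vapply(c(2, 1, 0.5), function(s)
    ctError(crop, voxelizeCtRoute(crop, c(s, s, s))), numeric(1))
  expect_true(all(diff(errs) < 0))

  expect_error(voxelizeCtRoute(crop, c(6, 6, 6)), "5 mm")
  expect_error(voxelizeCtRoute(crop, c(0, 1, 1)), "positive")
})
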