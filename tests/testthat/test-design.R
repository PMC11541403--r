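test_that("border blending sinks the boundary ring into the face", {
  toy <- toyCase()
  bl <- boundaryLoops(toy$nm)
  ringZ <- meshVertices(toy$nm)[bl$vertices, 3]
  # post-blend boundary ring sits blendDepth inside the face plane
  expect_true(all(ringZ > -toy$params@blendDepth * 1.1))
  expect_true(all(ringZ < -toy$params@blendDepth * 0.9))

  # a band covering the whole surface is refused
  small <- meshHemisphere(radius = 2, n = 24)
  expect_error(blendBorder(small, toy$plate, designParams(blendWidth = 3)),
               "proper subset")
  # no face under the border
  farPlate <- meshPlate(c(200, 300), c(200, 300), z0 = 0, nx = 10, ny = 10)
  expect_error(blendBorder(meshHemisphere(radius = 20, n = 32), farPlate),
               "not found")
})

test_that("the prosthesis solid matches an analytic signed-distance oracle", {
  toy <- toyCase()
  pm <- toy$pm
  expect_watertight(pm)
  # oracle: hemispheric shell clipped to the half-space above the plate,
  # integrated on an independent regular grid
  h <- 0.25
  xs <- seq(-21, 21, by = h)
  zs <- seq(h / 2, 21, by = h)
  count <- 0
  for (z in zs) {
    r2 <- outer(xs^2, xs^2, "+") + z^2
    count <- count + sum(r2 < 400 & r2 > 196)
  }
  oracleVol <- count * h^3
  expect_equal(meshVolume(pm), oracleVol, tolerance = 0.03)

  # subtraction contract: almost nothing of the PM sits inside the face solid
  inter <- noseforge:::booleanIntersect(pm, toy$fmSolid, resolution = 0.5)
  interVol <- if (nFaces(inter) > 0) meshVolume(inter) else 0
  expect_lt(interVol, 0.005 * meshVolume(pm))
})

test_that("the achieved prosthesis wall equals the 6 mm protocol value", {
  toy <- toyCase()
  set.seed(1)
  th <- measureThickness(toy$pm, 2000)
  expect_equal(th$median, 6, tolerance = 0.05)
})

test_that("doubling the wall parameter doubles the measured thickness", {
  toy <- toyCase()
  params2 <- designParams(prosthesisWall = 12, resolution = 0.5)
  pm2 <- buildProsthesisSolid(toy$nm, toy$fmSolid, params2)
  set.seed(2)
  th2 <- measureThickness(pm2, 2000)
  expect_equal(th2$median, 12, tolerance = 0.05)
})

test_that("the connecting surface seats seamlessly on the face", {
  toy <- toyCase()
  set.seed(3)
  sf <- seamlessFit(toy$pm, toy$fmSolid, nSamples = 1000)
  expect_gte(sf$fraction02, 0.95)
})

test_that("nostril sculpting removes the specified cylinders", {
  slab <- meshBox(c(-20, -20, 0), c(20, 20, 10))
  spec <- nostrilSpec(entry = rbind(c(-6, 0, 10), c(6, 0, 10)),
                      axis = rbind(c(0, 0, -1), c(0, 0, -1)),
                      radius = c(3, 3), depth = c(8, 8))
  out <- sculptNostrils(slab, spec, resolution = 0.25)
  expect_watertight(out)
  removed <- meshVolume(slab) - meshVolume(out)
  expect_equal(removed, 2 * pi * 3^2 * 8, tolerance = 0.05)

  # zero nostrils: unchanged; disjoint cylinder: error
  expect_identical(sculptNostrils(slab, nostrilSpec()), slab)
  far <- nostrilSpec(entry = rbind(c(500, 0, 0)), axis = rbind(c(0, 0, -1)),
                     radius = 3, depth = 5)
  expect_error(sculptNostrils(slab, far), "intersect")
})

test_that("mold generation yields two watertight shells with the protocol gap", {
  mold <- toyMold()
  expect_watertight(mold@anteriorShell)
  expect_watertight(mold@posteriorShell)
  # the 0.3 mm closure offset between the stretched borders
  expect_equal(moldClosureGap(mold), 0.3, tolerance = 0.05 / 0.3)
  # shells do not interpenetrate
  set.seed(4)
  sp <- sampleSurfacePoints(mold@anteriorShell, 2000)
  expect_gte(min(signedDistance(mold@posteriorShell, sp$points)), 0)
})

test_that("both mold shells have the 4 mm protocol wall", {
  mold <- toyMold()
  set.seed(5)
  expect_equal(measureThickness(mold@anteriorShell, 2000)$median, 4,
               tolerance = 0.05)
  expect_equal(measureThickness(mold@posteriorShell, 2000)$median, 4,
               tolerance = 0.05)
})

test_that("the mold cavity reproduces the prosthesis model", {
  mold <- toyMold()
  toy <- toyCase()
  set.seed(6)
  cf <- cavityFidelity(mold, toy$pm, 2000)
  expect_lt(cf$q95, 0.2)
  # casting simulation: the enclosed volume matches the PM
  cast <- castingCavity(mold, toy$pm, resolution = 0.5)
  expect_watertight(cast)
  expect_equal(meshVolume(cast), meshVolume(toy$pm), tolerance = 0.02)
})

test_that("mold export writes exactly two watertight STL shells", {
  mold <- toyMold()
  dir <- withr::local_tempdir()
  paths <- exportMold(mold, dir)
  expect_length(paths, 2)
  expect_setequal(basename(paths), c("mold_anterior.stl", "mold_posterior.stl"))
  expect_length(list.files(dir, pattern = "\\.stl$"), 2)
  for (p in paths) {
    back <- readMesh(p)
    expect_watertight(back)
  }
  # volumes preserved across export within float precision
  expect_equal(meshVolume(readMesh(paths[1])), meshVolume(mold@anteriorShell),
               tolerance = 1e-5)
})

test_that("design parameter validation enforces the protocol invariants", {
  expect_error(designParams(moldGap = 5, moldWall = 4), "moldGap")
  expect_error(designParams(blendDepth = 7, prosthesisWall = 6), "blendDepth")
  expect_error(designParams(prosthesisWall = -1), "positive")
  expect_error(nostrilSpec(entry = matrix(0, 3, 3), axis = matrix(1, 3, 3),
                           radius = rep(1, 3), depth = rep(1, 3)),
               "two nostrils")
})
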