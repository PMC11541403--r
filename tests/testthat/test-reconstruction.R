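test_that("erase_region removes exactly the masked vertices", {
  topo <- faceTopology(64, 64)
  gf <- generateFace(faceParams(), topo)
  n <- nVertices(gf$mesh)

  emptyMask <- RegionMask(rep(FALSE, n))
  expect_identical(eraseRegion(gf$mesh, emptyMask), gf$mesh)

  erased <- eraseRegion(gf$mesh, gf$noseMask)
  expect_equal(nVertices(erased), n - sum(gf$noseMask@flags))
  # the rhinectomy defect opens exactly one new boundary loop
  expect_equal(boundaryLoops(erased)$nLoops,
               boundaryLoops(gf$mesh)$nLoops + 1L)

  expect_error(eraseRegion(gf$mesh, RegionMask(rep(TRUE, n))), "every vertex")
  expect_error(eraseRegion(gf$mesh, RegionMask(TRUE)), "topology")
})

test_that("rigid landmark alignment recovers a known transform", {
  lm <- LandmarkSet(list(a = c(10, 0, 0), b = c(0, 12, 0), c = c(0, 0, 9),
                         d = c(5, 5, 5)))
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr0 <- new("RigidTransform", rotation = R, translation = c(4, -2, 7), scale = 1)
  moved <- applyTransform(tr0, lm)
  est <- rigidAlign(lm, moved)
  expect_equal(est@rotation, R, tolerance = 1e-6)
  expect_equal(est@translation, c(4, -2, 7), tolerance = 1e-6)

  ident <- rigidAlign(lm, lm)
  expect_equal(ident@rotation, diag(3), tolerance = 1e-9)
  expect_equal(ident@translation, c(0, 0, 0), tolerance = 1e-9)

  two <- LandmarkSet(list(a = c(1, 0, 0), b = c(0, 1, 0)))
  expect_error(rigidAlign(two, two), "3 shared")
  line <- LandmarkSet(list(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0)))
  expect_error(rigidAlign(line, line), "collinear")
})

test_that("fitting a full model instance recovers coefficients and surface", {
  pm <- popModel()
  m <- pm$model
  set.seed(5)
  cstar <- pmin(pmax(rnorm(modelRank(m)), -2), 2)
  inst <- sampleInstance(m, cstar)
  fit <- fitModel(m, inst, fitConfig(convergenceTol = 2e-4, maxIterations = 150))
  expect_lt(max(abs(fit@coefficients - cstar)), 0.05)
  expect_lt(rmsDistance(meshVertices(fit@fittedMesh), inst), 0.05)
})

test_that("strong regularization drives the fit to the aligned mean", {
  pm <- popModel()
  m <- pm$model
  set.seed(6)
  inst <- sampleInstance(m, rnorm(modelRank(m)))
  fit <- fitModel(m, inst, fitConfig(regularizationWeight = 1e9, maxIterations = 5))
  expect_lt(max(abs(fit@coefficients)), 1e-3)
})

test_that("a defect-masked instance is reconstructed in the erased region", {
  pm <- popModel()
  gt <- patientFace()
  set.seed(6)
  rh <- simulateRhinectomy(gt$mesh, gt$noseMask, margin = 3, noiseSd = 0.1)
  init <- rigidAlign(modelLandmarks(pm$model, pm$landmarkIdx), gt$landmarks)
  fit <- fitModel(pm$model, rh$fm, fitConfig(convergenceTol = 5e-4, maxIterations = 100),
                  init, excludeRegion = pm$noseMask)
  gtv <- meshVertices(gt$mesh)[rh$removed, , drop = FALSE]
  expect_lt(rmsDistance(gtv, fit@fittedMesh), 1.0)
  expect_error(
    fitModel(pm$model, rh$fm, fitConfig(), new("RigidTransform",
                                               translation = c(500, 0, 0))),
    "correspondences")
})

test_that("erased geometry never influences the fit (defect blindness)", {
  pm <- popModel()
  gt <- patientFace()
  # two scans differing only inside the defect region
  v2 <- meshVertices(gt$mesh)
  idx <- which(gt$noseMask@flags)
  set.seed(7)
  v2[idx, 3] <- v2[idx, 3] + rnorm(length(idx), 0, 5)  # pure noise in the defect
  noisy <- TriangleMesh(v2, meshFaces(gt$mesh))
  maskFull <- dilateRegion(gt$mesh, gt$noseMask, 3)
  fmA <- eraseRegion(gt$mesh, maskFull)
  fmB <- eraseRegion(noisy, maskFull)
  expect_identical(meshVertices(fmA), meshVertices(fmB))
  init <- rigidAlign(modelLandmarks(pm$model, pm$landmarkIdx), gt$landmarks)
  cfg <- fitConfig(maxIterations = 10)
  fitA <- fitModel(pm$model, fmA, cfg, init, excludeRegion = pm$noseMask)
  fitB <- fitModel(pm$model, fmB, cfg, init, excludeRegion = pm$noseMask)
  expect_identical(fitA@coefficients, fitB@coefficients)
})

test_that("the data-term RMS is non-increasing at fixed correspondences", {
  pm <- popModel()
  m <- pm$model
  set.seed(8)
  inst <- sampleInstance(m, rnorm(modelRank(m)))
  # one manual iteration at fixed vertex-to-closest-point correspondences
  W <- sweep(m@basis, 2, m@modeSD, "*")
  start <- meshVertices(meanMesh(m))
  q <- noseforge:::meshQuery(inst)
  cl <- noseforge:::cpp_closest(q, start)
  rmsBefore <- sqrt(mean(cl$distance^2))
  rows <- as.vector(t(outer(3 * (seq_len(nrow(start)) - 1), 1:3, "+")))
  A <- W[rows, , drop = FALSE]
  b <- as.vector(t(cl$point)) - m@mean[rows]
  co <- solve(crossprod(A) + diag(0.1, modelRank(m)), crossprod(A, b))
  # evaluate against the same fixed targets
  rmsAfter <- sqrt(mean(rowSums((matrix(m@mean + W %*% co, ncol = 3, byrow = TRUE) -
                                   cl$point)^2)))
  expect_lte(rmsAfter, rmsBefore + 1e-9)
})

test_that("crop_nose extracts exactly the flagged sub-mesh", {
  pm <- popModel()
  mean_ <- meanMesh(pm$model)
  allMask <- RegionMask(rep(TRUE, nVertices(mean_)))
  expect_equal(meshVertices(cropNose(mean_, allMask)), meshVertices(mean_))

  crop <- cropNose(mean_, pm$noseMask)
  expect_equal(nVertices(crop), sum(pm$noseMask@flags))

  # the cropped mean covers the generator-reported nose patch area
  gf <- generateFace(faceParams(), pm$topo)
  cropTight <- cropNose(gf$mesh, gf$noseMask)
  expect_equal(sum(faceAreas(cropTight)), gf$noseArea, tolerance = 0.10)

  expect_error(cropNose(mean_, RegionMask(rep(FALSE, nVertices(mean_)))), "empty")
})

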