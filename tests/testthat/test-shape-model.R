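# A small analytic training family for the model unit tests: spheres with
# two latent parameters (radius, z-elongation) on a shared topology.
sphereFamily <- function(n, seed) {
  base <- meshSphere(radius = 10, subdivisions = 2)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r <- 10 + rnorm(1, 0, 1)
    ez <- 1 + rnorm(1, 0, 0.08)
    v <- meshVertices(base) / 10
    TriangleMesh(cbind(r * v[, 1], r * v[, 2], r * ez * v[, 3]), meshFaces(base))
  })
}

test_that("Procrustes removes translations and PCA rank is bounded", {
  base <- meshSphere(radius = 10, subdivisions = 2)
  copies <- lapply(1:5, function(i)
    TriangleMesh(sweep(meshVertices(base), 2, c(i * 3, -i, i^2), "+"), meshFaces(base)))
  m <- buildModel(copies)
  expect_equal(modelRank(m), 0L)  # pure translations carry no shape variance
  expect_equal(meshVertices(sampleInstance(m, numeric(0))),
               sweep(meshVertices(base), 2, colMeans(meshVertices(base))),
               tolerance = 1e-8)

  fam <- sphereFamily(10, seed = 3)
  m2 <- buildModel(fam, rank = 100)
  expect_lte(modelRank(m2), 9L)
  expect_error(buildModel(fam[1]), "at least 2")
  bad <- fam
  bad[[2]] <- meshSphere(radius = 10, subdivisions = 1)
  expect_error(buildModel(bad), "topology")
})

test_that("a full-rank model reconstructs its training shapes by projection", {
  fam <- sphereFamily(8, seed = 5)
  m <- buildModel(fam, rank = 7)
  # re-align a training shape into model space, project, reconstruct
  x <- meshVertices(fam[[4]])
  xc <- sweep(x, 2, colMeans(x))
  mv <- meshVertices(meanMesh(m))
  tr <- noseforge:::kabsch(xc, mv)
  xa <- sweep(xc %*% t(tr$R), 2, tr$t, "+")
  co <- projectShape(m, as.vector(t(xa)))
  rec <- sampleInstance(m, co)
  expect_lt(sqrt(mean((meshVertices(rec) - xa)^2)), 1e-6)
})

test_that("sampling is linear in the coefficients", {
  fam <- sphereFamily(10, seed = 7)
  m <- buildModel(fam)
  r <- modelRank(m)
  expect_equal(meshVertices(sampleInstance(m, rep(0, r))),
               meshVertices(meanMesh(m)))
  set.seed(8)
  co <- rnorm(r)
  plus <- meshVertices(sampleInstance(m, co))
  minus <- meshVertices(sampleInstance(m, -co))
  expect_equal((plus + minus) / 2, meshVertices(meanMesh(m)), tolerance = 1e-9)
  expect_error(sampleInstance(m, rep(0, r + 1)), "rank")
})

test_that("Monte-Carlo sampling reproduces the model-implied variance", {
  fam <- sphereFamily(12, seed = 9)
  m <- buildModel(fam)
  r <- modelRank(m)
  set.seed(10)
  n <- 500
  acc <- matrix(0, length(m@mean), 2)
  for (i in seq_len(n)) {
    x <- m@mean + as.vector(m@basis %*% (rnorm(r) * m@modeSD))
    acc[, 1] <- acc[, 1] + x
    acc[, 2] <- acc[, 2] + x^2
  }
  empSD <- sqrt(pmax(acc[, 2] / n - (acc[, 1] / n)^2, 0))
  implied <- sqrt(rowSums(sweep(m@basis, 2, m@modeSD, "*")^2))
  sel <- implied > median(implied)  # avoid ratios of near-zero SDs
  expect_lt(median(abs(empSD[sel] / implied[sel] - 1)), 0.10)
})

test_that("parameter recovery by projection is exact within +/- 2 SD", {
  fam <- sphereFamily(10, seed = 12)
  m <- buildModel(fam)
  set.seed(13)
  for (i in 1:5) {
    co <- runif(modelRank(m), -2, 2)
    rec <- projectShape(m, sampleInstance(m, co))
    expect_lt(max(abs(rec - co)), 1e-6)
  }
})

test_that("a mirrored training set yields the mirrored mean", {
  fam <- sphereFamily(8, seed = 14)
  mir <- lapply(fam, function(msh) {
    v <- meshVertices(msh)
    v[, 1] <- -v[, 1]
    TriangleMesh(v, meshFaces(msh)[, c(1, 3, 2)])  # keep outward winding
  })
  m1 <- buildModel(fam)
  m2 <- buildModel(mir)
  mv1 <- meshVertices(meanMesh(m1))
  mv2 <- meshVertices(meanMesh(m2))
  mv2[, 1] <- -mv2[, 1]
  # identical up to the Procrustes alignment of the mean
  tr <- noseforge:::kabsch(mv2, mv1)
  aligned <- sweep(mv2 %*% t(tr$R), 2, tr$t, "+")
  expect_lt(max(abs(aligned - mv1)), 1e-6)
})

test_that("augmentation adds smooth modes without shrinking the span", {
  pm <- popModel()
  m <- pm$model
  ker <- smoothDeformationKernel(variance = 1, lengthScale = 30, approxRank = 24)
  aug <- augmentModel(m, ker)
  expect_equal(modelRank(aug), modelRank(m) + 24L)
  expect_lt(max(abs(crossprod(aug@basis) - diag(modelRank(aug)))), 1e-8)
  expect_true(all(diff(modeSD(aug)) <= 1e-9))

  # conservation: a base-model sample stays exactly representable
  set.seed(20)
  x <- noseforge:::flattenMesh(sampleInstance(m, rnorm(modelRank(m)))) - aug@mean
  resid <- x - aug@basis %*% crossprod(aug@basis, x)
  expect_lt(sqrt(mean(resid^2)), 1e-9)

  # degenerate kernel: variance 0 leaves the model untouched
  expect_identical(augmentModel(m, smoothDeformationKernel(variance = 0)), m)
  expect_error(augmentModel(m, smoothDeformationKernel(approxRank = 1e9)),
               "exceeds")
})

test_that("augmentation lets the model reach an out-of-span smooth bump", {
  pm <- popModel()
  m <- pm$model
  mv <- meshVertices(meanMesh(m))
  # a smooth bump on the cheek, outside the PCA span
  bump <- 2 * exp(-((mv[, 1] - 35)^2 + (mv[, 2] + 10)^2) / 15^2)
  target <- as.vector(t(mv + cbind(0, 0, bump))) - m@mean
  residBase <- target - m@basis %*% crossprod(m@basis, target)
  aug <- augmentModel(m, smoothDeformationKernel(variance = 1, lengthScale = 30,
                                                 approxRank = 45))
  residAug <- target - aug@basis %*% crossprod(aug@basis, target)
  expect_lt(sqrt(sum(residAug^2)), 0.8 * sqrt(sum(residBase^2)))
})

test_that("posterior conditioning honours constraints and shrinks variance", {
  pm <- popModel()
  m <- pm$model
  expect_identical(posteriorModel(m, integer(0), matrix(numeric(0), 0, 3), 0.1), m)

  set.seed(21)
  truth <- sampleInstance(m, rnorm(modelRank(m)))
  ids <- pm$landmarkIdx
  obs <- meshVertices(truth)[ids, , drop = FALSE]
  post <- posteriorModel(m, ids, obs, noiseSd = 0.01)
  postAt <- meshVertices(meanMesh(post))[ids, , drop = FALSE]
  # near-interpolation in the small-noise limit
  expect_lt(max(sqrt(rowSums((postAt - obs)^2))), 10 * 0.01)
  # every posterior mode variance is bounded by the prior counterpart
  expect_true(all(modeSD(post) <= modeSD(m)[seq_along(modeSD(post))] + 1e-9))
  expect_error(posteriorModel(m, ids, obs, noiseSd = 0), "positive")
})

test_that("model archives round-trip with nose mask and landmarks", {
  pm <- popModel()
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(pm$model, f, noseMask = pm$noseMask, landmarkIndices = pm$landmarkIdx)
  back <- loadModel(f)
  expect_equal(back$model@mean, pm$model@mean)
  expect_equal(back$model@basis, pm$model@basis)
  expect_identical(back$noseMask@flags, pm$noseMask@flags)
  expect_identical(back$landmarkIndices, pm$landmarkIdx)
})
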