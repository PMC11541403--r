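test_that("STL, PLY and OBJ round-trips preserve geometry", {
  cube <- meshBox(c(0, 0, 0), c(1, 1, 1))
  hemi <- meshHemisphere(radius = 10, n = 24)
  for (fmt in c("stl", "ply", "obj")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeMesh(cube, f)
    back <- readMesh(f)
    expect_equal(nVertices(back), 8L, info = fmt)
    expect_equal(nFaces(back), 12L, info = fmt)
    expect_equal(meshVolume(back), 1, tolerance = 1e-6)
    expect_true(isWatertight(back), info = fmt)

    f2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeMesh(hemi, f2)
    back2 <- readMesh(f2)
    # maximum vertex deviation after welding is within float precision
    expect_lt(hausdorffDistance(hemi, back2), 1e-4)
  }
})

test_that("PLY carries per-vertex region labels", {
  m <- meshBox()
  m@vertexLabels <- rep(c(0L, 1L), 4)
  f <- withr::local_tempfile(fileext = ".ply")
  writeMesh(m, f)
  back <- readMesh(f)
  expect_equal(sort(unique(back@vertexLabels)), c(0L, 1L))
})

test_that("malformed and empty meshes are refused", {
  empty <- TriangleMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  f <- withr::local_tempfile(fileext = ".stl")
  expect_error(writeMesh(empty, f), "empty")

  # truncated binary STL: header promises more triangles than present
  writeMesh(meshBox(), f)
  raw <- readBin(f, "raw", file.size(f))
  truncated <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw[1:(length(raw) - 30)], truncated)
  expect_error(readMesh(truncated), "truncated")

  garbagePly <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5"), garbagePly)
  expect_error(readMesh(garbagePly), "PLY")

  expect_error(readMesh(withr::local_tempfile(fileext = ".stl")), "not found")
})

test_that("landmark JSON round-trips", {
  lm <- LandmarkSet(list(glabella = c(0, 40, 50), pogonion = c(0, -70, 40),
                         exocanthion_left = c(45, 30, 40)))
  f <- withr::local_tempfile(fileext = ".json")
  writeLandmarks(lm, f)
  back <- readLandmarks(f)
  expect_equal(back@coords, lm@coords)
})
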