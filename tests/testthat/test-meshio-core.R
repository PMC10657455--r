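test_that("mesh write/read round-trips preserve geometry across formats", {
  cube <- unitCube()
  for (ext in c("stl", "ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeMesh(cube, path)
    back <- readMesh(path)
    expect_equal(nrow(meshFaces(back)), 12L, info = ext)
    expect_equal(nrow(meshVertices(back)), 8L, info = ext)
    expect_equal(surfaceArea(back), 6, tolerance = 1e-7, info = ext)
    expect_equal(enclosedVolume(back), 1, tolerance = 1e-7, info = ext)
  }
})

test_that("unit scale is applied on load", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeMesh(unitCube(), path)
  um <- readMesh(path, unitScale = 1000)
  expect_equal(enclosedVolume(um), 1e9, tolerance = 1e-6)
})

test_that("unsupported and malformed mesh inputs error cleanly", {
  expect_error(readMesh(withr::local_tempfile(fileext = ".xyz")), "cannot read")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("0 0 0", bad)
  expect_error(readMesh(bad), "unsupported")
  empty <- TriMesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3))
  tmp <- withr::local_tempfile(fileext = ".stl")
  expect_error(writeMesh(empty, tmp), "empty")
})

test_that("a lone-triangle ASCII STL reads back and is flagged non-watertight", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeMesh(singleTriangle(), path)
  m <- readMesh(path)
  expect_equal(nrow(meshFaces(m)), 1L)
  rep <- validateMesh(m)
  expect_false(rep@watertight)
})

test_that("validateMesh reports watertightness, orientation and Euler characteristic", {
  cube <- unitCube()
  rep <- validateMesh(cube)
  expect_true(rep@watertight)
  expect_true(rep@oriented)
  expect_identical(rep@eulerCharacteristic, 2L)
  expect_identical(rep@nDegenerateFaces, 0L)

  holed <- cube
  holed@faces <- holed@faces[-1L, ]
  expect_false(validateMesh(holed)@watertight)

  flipped <- cube
  flipped@faces[1L, ] <- flipped@faces[1L, c(1, 3, 2)]
  expect_false(validateMesh(flipped)@oriented)
})

test_that("degenerate faces are removed during validation with a warning", {
  cube <- unitCube()
  degen <- TriMesh(meshVertices(cube),
                   rbind(meshFaces(cube), c(1L, 1L, 2L)))
  expect_warning(rep <- validateMesh(degen), "degenerate")
  expect_identical(rep@nDegenerateFaces, 1L)
  expect_true(rep@watertight)  # after cleaning
})

test_that("surface area and enclosed volume match closed forms", {
  cube <- unitCube()
  expect_equal(surfaceArea(cube), 6)
  expect_equal(enclosedVolume(cube), 1)
  expect_equal(surfaceArea(singleTriangle()), 0.5)
  far <- translateMesh(cube, c(1e6, 1e6, 1e6))
  expect_equal(enclosedVolume(far), 1, tolerance = 1e-9)
  expect_equal(surfaceArea(cube, units = "um2"), 6e-6)
  expect_equal(enclosedVolume(cube, units = "um3"), 1e-9)
})

test_that("metric operations refuse open or inverted meshes unless forced", {
  holed <- unitCube()
  holed@faces <- holed@faces[-1L, ]
  expect_error(enclosedVolume(holed), "not watertight")
  expect_equal(enclosedVolume(holed, force = TRUE), 1, tolerance = 0.2)
  inverted <- unitCube()
  inverted@faces <- inverted@faces[, c(1, 3, 2)]
  expect_error(enclosedVolume(inverted), "orient")
  expect_warning(v <- enclosedVolume(inverted, fixOrientation = TRUE),
                 "inward")
  expect_equal(v, 1)
})

test_that("area and volume are invariant under rigid motion and scale correctly", {
  set.seed(11)
  m <- makeIcosphere(3, 3)
  a0 <- surfaceArea(m); v0 <- enclosedVolume(m)
  for (i in 1:5) {
    R <- randomRotationMatrix()
    m2 <- translateMesh(rotateMesh(m, R), stats::rnorm(3, sd = 1e5))
    expect_equal(surfaceArea(m2), a0, tolerance = 1e-9)
    expect_equal(enclosedVolume(m2), v0, tolerance = 1e-9)
  }
  s <- 3.7
  ms <- scaleMesh(m, s)
  expect_equal(surfaceArea(ms), a0 * s^2, tolerance = 1e-12)
  expect_equal(enclosedVolume(ms), v0 * s^3, tolerance = 1e-12)
})

test_that("icosphere metrics converge monotonically to the analytic sphere", {
  errs <- vapply(0:4, function(s)
    abs(surfaceArea(makeIcosphere(1, s)) - 4 * pi) / (4 * pi), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[5], 0.005)
  expect_lt(abs(enclosedVolume(makeIcosphere(1, 4)) - 4 * pi / 3) / (4 * pi / 3),
            0.005)
})

test_that("labelsToMeshes extracts closed meshes whose volume matches the voxel count", {
  vox <- array(0L, dim = c(14, 14, 14))
  vox[3:12, 3:12, 3:12] <- 1L
  lv <- LabelVolume(vox, 10, c(cube = 1L))
  scene <- labelsToMeshes(lv)
  m <- sceneMeshes(scene)$cube
  rep <- validateMesh(m)
  expect_true(rep@watertight)
  expect_true(rep@oriented)
  vtrue <- voxelLabelVolume(lv, 1L)
  expect_equal(vtrue, 1e6 * 10^3 / 1e3)  # 1000 voxels * 10^3 nm^3
  expect_lt(abs(enclosedVolume(m) - vtrue) / vtrue, 0.05)
  expect_error(labelsToMeshes(lv, labels = 7L), "absent")
})

test_that("a rasterized sphere's extracted mesh volume is within 2% of analytic", {
  n <- 64L
  idx <- seq_len(n) - 1
  co <- expand.grid(z = idx, y = idx, x = idx)
  r <- 25
  r2 <- (co$x - 31.5)^2 + (co$y - 31.5)^2 + (co$z - 31.5)^2
  lv <- LabelVolume(array(as.integer(r2 <= r^2), dim = c(n, n, n)), 8,
                    c(sphere = 1L))
  m <- sceneMeshes(labelsToMeshes(lv))$sphere
  vtrue <- 4 / 3 * pi * (r * 8)^3
  expect_lt(abs(enclosedVolume(m) - vtrue) / vtrue, 0.02)
})

test_that("voxelLabelVolume is exact and errors on absent labels", {
  vox <- array(0L, dim = c(25, 25, 25))
  vox[2:21, 2:21, 2:21] <- 3L
  lv <- LabelVolume(vox, 7, c(blob = 3L))
  expect_identical(voxelLabelVolume(lv, 3L), 20^3 * 7^3)
  expect_error(voxelLabelVolume(lv, 1L), "not present")
})

test_that("label volumes round-trip through NRRD and TIFF", {
  vox <- array(0L, dim = c(6, 7, 8))
  vox[2:4, 3:5, 2:6] <- 2L
  lv <- LabelVolume(vox, 8, c(x = 2L))
  nr <- withr::local_tempfile(fileext = ".nrrd")
  writeLabelVolume(lv, nr)
  back <- readLabelVolume(nr, labelMap = c(x = 2L))
  expect_identical(back@voxels, lv@voxels)
  expect_equal(back@voxelSize, 8)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeLabelVolume(lv, tf)
  back2 <- readLabelVolume(tf, voxelSize = 8, labelMap = c(x = 2L))
  expect_identical(back2@voxels, lv@voxels)
})
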