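test_that("icospheres are watertight, oriented and analytic at modest depth", {
  ico <- makeIcosphere(1, 0)
  expect_identical(nrow(meshFaces(ico)), 20L)
  rep <- validateMesh(ico)
  expect_true(rep@watertight)
  expect_true(rep@oriented)
  expect_identical(rep@eulerCharacteristic, 2L)
  s4 <- makeIcosphere(1, 4)
  expect_lt(abs(surfaceArea(s4) - 4 * pi) / (4 * pi), 0.005)
  expect_error(makeIcosphere(1, 10), "subdivisions")
  expect_error(makeIcosphere(-1, 2), "radius")
})

test_that("generators are deterministic under a fixed seed", {
  a <- makeWrinkledSphere(2000, WrinkleGenParams(nRidges = 10, seed = 9))
  b <- makeWrinkledSphere(2000, WrinkleGenParams(nRidges = 10, seed = 9))
  expect_identical(meshVertices(a), meshVertices(b))
  expect_identical(attr(a, "groundTruth"), attr(b, "groundTruth"))
  c1 <- makeToyCyst(ToyCystConfig(nLDs = 10L, LDFraction = 0.01, seed = 4L))
  c2 <- makeToyCyst(ToyCystConfig(nLDs = 10L, LDFraction = 0.01, seed = 4L))
  expect_identical(lapply(sceneMeshes(c1), meshVertices),
                   lapply(sceneMeshes(c2), meshVertices))
})

test_that("a ridge-free configuration returns the plain sphere", {
  w <- makeWrinkledSphere(2000, WrinkleGenParams(nRidges = 0, seed = 1))
  expect_equal(surfaceArea(w), attr(w, "baseArea"))
  expect_identical(nrow(attr(w, "groundTruth")), 0L)
})

test_that("sampled ridge dimensions track the configured Gaussians", {
  expect_warning(
    w <- makeWrinkledSphere(9400, WrinkleGenParams(nRidges = 60, seed = 42),
                            subdivisions = 5),  # coarse mesh: only the table matters
    "under-resolved")
  gt <- attr(w, "groundTruth")
  expect_identical(nrow(gt), 60L)
  expect_lt(abs(mean(gt$length) - 406), 2 * 90.9 / sqrt(60))
  expect_true(all(gt$length >= 406 - 2 * 90.9 & gt$length <= 406 + 2 * 90.9))
  expect_true(all(gt$width > 0 & gt$width <= gt$length))
  # non-intersection: conservative disc separation between ridge centres
  ctr <- as.matrix(gt[, c("cx", "cy", "cz")]) / 9400
  ang <- acos(pmin(pmax(tcrossprod(ctr), -1), 1)) * 9400
  sep <- outer(gt$length, gt$length, "+") / 2
  off <- ang - sep
  diag(off) <- Inf
  expect_true(all(off > 0))
})

test_that("wrinkled spheres strictly gain area over the base sphere", {
  w <- makeWrinkledSphere(2500, WrinkleGenParams(nRidges = 30, seed = 2))
  expect_gt(surfaceArea(w), attr(w, "baseArea"))
})

test_that("the two-sphere scene has the analytic gap and survives (de)serialization", {
  sc <- makeTwoSphereScene(1, 1, 3, subdivisions = 4)
  d <- vertexToSurfaceDistances(sceneMeshes(sc)$A, sceneMeshes(sc)$B)
  expect_equal(min(d), 1, tolerance = 0.01)
  expect_false(sc@metadata$overlapping)
  dir <- withr::local_tempdir()
  writeScene(sc, dir)
  back <- readScene(dir)
  expect_identical(meshFaces(sceneMeshes(back)$B), meshFaces(sceneMeshes(sc)$B))
  expect_equal(meshVertices(sceneMeshes(back)$A), meshVertices(sceneMeshes(sc)$A),
               tolerance = 1e-9)
})

test_that("the toy cyst is geometrically consistent with its ground truth", {
  sc <- defaultToyCyst()
  gt <- sc@metadata$groundTruth
  meshes <- sceneMeshes(sc)
  Vcell <- enclosedVolume(cellBoundary(sc))
  expect_true(validateMesh(cellBoundary(sc))@watertight)
  ok <- vapply(meshes, function(m) validateMesh(m)@watertight, logical(1))
  expect_true(all(ok))
  # organelles fit in the cell
  vols <- vapply(meshes, enclosedVolume, numeric(1))
  expect_lt(sum(vols) / Vcell, 1)
  # every mesh volume within 2% of its generator reference
  for (nm in names(meshes)) {
    ref <- gt$volume_nm3[gt$name == nm]
    expect_lt(abs(vols[[nm]] - ref) / ref, 0.02)
  }
  # mitochondria parked at the configured gap from the starch-filled tips
  mito <- cystmorph:::.mergeClass(sc, "mitochondrion")
  starch <- cystmorph:::.mergeClass(sc, "starch")
  gap <- sc@metadata$proximity_offset_nm
  expect_lt(abs(distanceExtrema(mito, starch)[["min"]] - gap) / gap, 0.1)
})

test_that("rasterize -> remesh round trip preserves volumes within 5%", {
  s1 <- makeIcosphere(400, 4, center = c(600, 600, 600), name = "a")
  s2 <- makeEllipsoid(c(300, 220, 180), 4, center = c(1500, 600, 600),
                      name = "b")
  sc <- OrganelleScene(list(a = s1, b = s2))
  lv <- rasterizeScene(sc, 15)
  expect_identical(sort(unname(lv@labelMap)), c(1L, 2L))
  # background fills the exterior (label 0 dominates the corners)
  expect_identical(lv@voxels[1, 1, 1], 0L)
  back <- labelsToMeshes(lv)
  for (nm in c("a", "b")) {
    v0 <- enclosedVolume(sc@meshes[[nm]])
    v1 <- enclosedVolume(sceneMeshes(back)[[nm]])
    v2 <- voxelLabelVolume(lv, lv@labelMap[[nm]])
    expect_lt(abs(v1 - v0) / v0, 0.05)
    expect_lt(abs(v2 - v0) / v0, 0.05)
  }
})

test_that("rasterization rejects a voxel size too coarse for the thinnest structure", {
  sc <- OrganelleScene(list(tiny = makeIcosphere(10, 2, center = c(50, 50, 50),
                                                 name = "tiny")))
  expect_error(rasterizeScene(sc, 15), "voxelSize too coarse")
})

test_that("nested organelles keep their labels under priority rasterization", {
  inner <- makeIcosphere(100, 3, center = c(400, 400, 400), name = "inner")
  outer <- makeIcosphere(300, 3, center = c(400, 400, 400), name = "outer")
  lv <- rasterizeScene(OrganelleScene(list(outer = outer, inner = inner)), 20)
  expect_gt(voxelLabelVolume(lv, lv@labelMap[["inner"]]),
            0.9 * 4 / 3 * pi * 100^3)
})
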