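test_that("distance to itself is zero and extrema behave on translated copies", {
  cube <- unitCube()
  expect_equal(vertexToSurfaceDistances(cube, cube), rep(0, 8))
  expect_equal(bruteForceDistances(cube, cube), rep(0, 8))
  far <- translateMesh(cube, c(5, 0, 0))
  ex <- distanceExtrema(far, cube)
  expect_equal(unname(ex["min"]), 4)
  sph <- makeIcosphere(1, 3)
  expect_equal(unname(distanceExtrema(sph, sph)), c(0, 0))
})

test_that("single-triangle target distances match the closed form", {
  tri <- singleTriangle()
  pts <- TriMesh(rbind(c(0.25, 0.25, 2),   # above interior -> plane distance
                       c(-1, -1, 0),       # beyond vertex A
                       c(2, 2, 0)),        # beyond edge BC
                 rbind(c(1L, 2L, 3L)))
  d <- vertexToSurfaceDistances(pts, tri)
  expect_equal(d[1], 2)
  expect_equal(d[2], sqrt(2))
  expect_equal(d[3], 3 / sqrt(2))  # closest point is midpoint of hypotenuse
  expect_equal(bruteForceDistances(pts, tri), d)
})

test_that("accelerated distances equal the brute-force oracle on random scenes", {
  for (seed in 1:20) {
    set.seed(seed)
    A <- makeIcosphere(stats::runif(1, 0.5, 2), 2, center = stats::rnorm(3))
    B <- makeEllipsoid(stats::runif(3, 0.4, 2), 2,
                       center = stats::rnorm(3, sd = 2),
                       axes = randomRotationMatrix())
    fast <- vertexToSurfaceDistances(A, B)
    slow <- bruteForceDistances(A, B)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("the brute-force oracle refuses oversized problems unless forced", {
  big <- makeIcosphere(1, 5)
  expect_error(bruteForceDistances(big, big), "guard")
})

test_that("two-sphere gap distances match the analytic values", {
  sc <- makeTwoSphereScene(1, 1, 3, subdivisions = 4)
  A <- sceneMeshes(sc)$A; B <- sceneMeshes(sc)$B
  ex <- distanceExtrema(A, B)
  expect_equal(unname(ex["min"]), 1, tolerance = 0.01)
  expect_equal(unname(ex["max"]), 3, tolerance = 0.01)
  # symmetry of the minimum (maxima need not match)
  exBA <- distanceExtrema(B, A)
  expect_equal(unname(ex["min"]), unname(exBA["min"]), tolerance = 0.01)
})

test_that("proximity fractions match the spherical-cap closed form", {
  set.seed(99)
  for (i in 1:10) {
    rA <- stats::runif(1, 0.5, 2)
    rB <- stats::runif(1, 0.5, 2)
    d <- (rA + rB) * stats::runif(1, 1.1, 1.8)
    gap <- d - rA - rB
    repeat {  # keep the cap moderate so the closed form is the dominant term
      t <- stats::runif(1, gap * 0.5 + 0.01, gap + rB)
      want <- sphereCapFraction(rA, rB, d, t)
      if (want > 0.02 && want < 0.35) break
    }
    sc <- makeTwoSphereScene(rA, rB, d, subdivisions = 5)
    pr <- proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B, thresholds = t)
    expect_lt(abs(pr@areaFractions - want), 0.01)
  }
})

test_that("an effectively infinite threshold flags the whole surface", {
  sc <- makeTwoSphereScene(1, 1, 3, subdivisions = 3)
  pr <- proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B, thresholds = 1e12)
  expect_equal(unname(pr@areaFractions), 1)
})

test_that("fractions are monotone in threshold and 24 nm faces are a subset of 100 nm faces", {
  sc <- makeTwoSphereScene(100, 80, 250, subdivisions = 4)
  pr <- proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B,
                     thresholds = c(100, 24))
  fr <- pr@areaFractions
  expect_lte(fr[2], fr[1])
  expect_true(all(pr@faceFlags[pr@faceFlags[, 2], 1]))
  expect_equal(pr@exclusiveFractions[1], fr[1] - fr[2])
  expect_error(proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B,
                            thresholds = numeric()), "threshold")
})

test_that("overlapping meshes yield zero distances with a warning", {
  sc <- makeTwoSphereScene(1, 1, 1.2, subdivisions = 3)
  expect_true(sc@metadata$overlapping)
  expect_warning(pr <- proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B,
                                    thresholds = 0.5),
                 "overlap")
  expect_equal(pr@minDistance, 0)
})

test_that("proximity results serialize to CSV/JSON and scalar-annotated PLY", {
  sc <- makeTwoSphereScene(1, 1, 3, subdivisions = 2)
  pr <- proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B,
                     thresholds = c(1.5, 1.1))
  dir <- withr::local_tempdir()
  files <- writeProximityResult(pr, source = sceneMeshes(sc)$A,
                                prefix = file.path(dir, "ab"),
                                writePLY = TRUE)
  expect_true(all(file.exists(files)))
  js <- jsonlite::fromJSON(files[2])
  expect_equal(js$area_fractions, unname(pr@areaFractions))
  ply <- readMesh(files[3])
  expect_identical(meshFaces(ply), meshFaces(sceneMeshes(sc)$A))
})
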