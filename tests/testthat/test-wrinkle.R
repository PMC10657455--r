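test_that("zero smoothing iterations return the mesh unchanged", {
  m <- makeIcosphere(5, 3)
  out <- hcLaplacianSmooth(m, SmoothingParams(iterations = 0))
  expect_identical(meshVertices(out), meshVertices(m))
  expect_identical(meshFaces(out), meshFaces(m))
})

test_that("smoothing preserves connectivity and barely moves a smooth sphere", {
  m <- makeIcosphere(1, 4)
  s <- hcLaplacianSmooth(m, SmoothingParams(3))
  expect_identical(meshFaces(s), meshFaces(m))
  expect_identical(nrow(meshVertices(s)), nrow(meshVertices(m)))
  expect_lt(abs(surfaceArea(s) - surfaceArea(m)) / surfaceArea(m), 0.01)
})

test_that("the HC push-back loses far less volume than plain Laplacian smoothing", {
  m <- makeIcosphere(1, 3)
  v0 <- enclosedVolume(m)
  lossHC <- 1 - enclosedVolume(hcLaplacianSmooth(m, SmoothingParams(3))) / v0
  lossPlain <- 1 - enclosedVolume(laplacianSmooth(m, 3)) / v0
  expect_lt(abs(lossHC), lossPlain / 10)
})

test_that("smoothing a wrinkled sphere shrinks its area towards the base sphere", {
  w <- makeWrinkledSphere(3000, WrinkleGenParams(nRidges = 60, seed = 7))
  base <- attr(w, "baseArea")
  expect_gt(surfaceArea(w), base)  # relief strictly adds area
  s <- hcLaplacianSmooth(w, SmoothingParams(3))
  expect_lt(surfaceArea(s), surfaceArea(w))        # strictly decreases
  expect_lt(abs(surfaceArea(s) - base) / base, 0.03)
})

test_that("invalid smoothing parameters and isolated vertices are rejected", {
  expect_error(SmoothingParams(iterations = -1), "iterations")
  expect_error(SmoothingParams(alpha = 1.5), "alpha")
  lonely <- TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(9, 9, 9)),
                    rbind(c(1L, 2L, 3L)))
  expect_error(hcLaplacianSmooth(lonely, SmoothingParams(1)), "isolated")
})

test_that("wrinkle area gain matches direct arithmetic and is zero on identity", {
  expect_equal(wrinkleAreaGain(825.5, 736), 100 * (825.5 - 736) / 736)
  m <- makeIcosphere(2, 3)
  expect_identical(wrinkleAreaGain(m, m), 0)
  expect_warning(g <- wrinkleAreaGain(700, 736), "negative")
  expect_lt(g, 0)
  expect_error(wrinkleAreaGain(1, 0), "positive")
})

test_that("mean curvature matches the analytic sphere value and scaling law", {
  H1 <- vertexMeanCurvature(makeIcosphere(10, 4))
  expect_lt(max(abs(H1 * 10 - 1)), 0.05)
  H2 <- vertexMeanCurvature(makeIcosphere(20, 4))
  expect_equal(mean(H2) / mean(H1), 0.5, tolerance = 1e-6)
})

test_that("interior of a flat patch has near-zero mean curvature", {
  # open triangulated square grid; only interior vertices are meaningful
  n <- 8
  g <- expand.grid(x = 0:n, y = 0:n)
  idx <- function(i, j) i + 1L + (n + 1L) * j
  f <- do.call(rbind, lapply(0:(n - 1), function(j)
    do.call(rbind, lapply(0:(n - 1), function(i)
      rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
            c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  plane <- TriMesh(cbind(g$x, g$y, 0), f)
  H <- vertexMeanCurvature(plane)
  interior <- which(g$x > 0 & g$x < n & g$y > 0 & g$y < n)
  expect_lt(max(abs(H[interior])), 1e-9)
})

test_that("a smooth icosphere contains no wrinkle components", {
  ws <- detectWrinkles(makeIcosphere(2000, 4))
  expect_identical(ws@nComponents, 0L)
})

test_that("the detector recovers the ridge count and dimensions of a synthetic sphere", {
  w <- makeWrinkledSphere(3000, WrinkleGenParams(nRidges = 60, seed = 42))
  gt <- attr(w, "groundTruth")
  ws <- detectWrinkles(w)
  expect_gt(ws@nComponents, 0.9 * 60)
  expect_lt(ws@nComponents, 1.1 * 60)
  expect_lt(abs(ws@meanLength - mean(gt$length)) / mean(gt$length), 0.1)
  expect_lt(abs(ws@meanWidth - mean(gt$width)) / mean(gt$width), 0.1)
  expect_true(all(ws@components$length + 1e-9 >= ws@components$width))
  # summary statistics are recomputable from the component table
  expect_equal(ws@meanLength, mean(ws@components$length))
  expect_equal(ws@sdLength, stats::sd(ws@components$length))
})

test_that("ridge-dimension recovery holds across seeds (median error within 10%)", {
  errL <- errW <- numeric(10)
  for (i in 1:10) {
    w <- makeWrinkledSphere(3000, WrinkleGenParams(nRidges = 40, seed = 100 + i))
    gt <- attr(w, "groundTruth")
    ws <- detectWrinkles(w)
    errL[i] <- abs(ws@meanLength - mean(gt$length)) / mean(gt$length)
    errW[i] <- abs(ws@meanWidth - mean(gt$width)) / mean(gt$width)
  }
  expect_lte(stats::median(errL), 0.1)
  expect_lte(stats::median(errW), 0.1)
})

test_that("wrinkle statistics serialize to JSON", {
  w <- makeWrinkledSphere(2000, WrinkleGenParams(nRidges = 15, seed = 3))
  ws <- detectWrinkles(w)
  js <- jsonlite::fromJSON(wrinkleStatsJSON(ws))
  expect_equal(js$n_components, ws@nComponents)
  expect_equal(js$mean_length_nm, ws@meanLength)
})
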