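test_that("occupancies are organelle volume over cell volume", {
  cell <- scaleMesh(unitCube(), 10)           # volume 1000
  # two cubes of volume 100 and 300 inside the cell
  a <- translateMesh(scaleMesh(unitCube(), 100^(1 / 3)), c(1, 1, 1))
  b <- translateMesh(scaleMesh(unitCube(), 300^(1 / 3)), c(6, 6, 6))
  sc <- OrganelleScene(list(a = a, b = b), cellBoundary = cell)
  rep <- occupancyReport(sc)
  occ <- stats::setNames(rep@perOrganelle$occupancy, rep@perOrganelle$name)
  expect_equal(unname(occ["a"]), 0.1, tolerance = 1e-9)
  expect_equal(unname(occ["b"]), 0.3, tolerance = 1e-9)
})

test_that("an empty organelle set yields an empty table, a missing boundary errors", {
  cell <- scaleMesh(unitCube(), 10)
  rep <- occupancyReport(OrganelleScene(list(), cellBoundary = cell))
  expect_identical(nrow(rep@perOrganelle), 0L)
  expect_error(occupancyReport(OrganelleScene(list(a = cell))), "boundary")
})

test_that("an organelle larger than its cell is rejected as inconsistent", {
  cell <- unitCube()
  big <- scaleMesh(unitCube(), 2)
  expect_error(occupancyReport(OrganelleScene(list(big = big),
                                              cellBoundary = cell)),
               "exceeds the cell volume")
})

test_that("organelle ratios follow the scaling laws and reciprocity", {
  sc <- OrganelleScene(list(big = makeIcosphere(2, 4, name = "big"),
                            small = makeIcosphere(1, 4, center = c(10, 0, 0),
                                                  name = "small")))
  r <- organelleRatios(sc, "big", "small")
  expect_equal(r$volume_ratio, 8, tolerance = 1e-9)
  expect_equal(r$area_ratio, 4, tolerance = 1e-9)
  same <- organelleRatios(sc, "big", "big")
  expect_identical(same$volume_ratio, 1)
  inv <- organelleRatios(sc, "small", "big")
  expect_equal(r$volume_ratio * inv$volume_ratio, 1, tolerance = 1e-9)
  expect_error(organelleRatios(sc, "big", "nope"), "absent")
})

test_that("multi-component organelle classes aggregate before ratios", {
  m1 <- makeIcosphere(1, 3, center = c(0, 0, 0), name = "mito_1")
  m2 <- makeIcosphere(1, 3, center = c(5, 0, 0), name = "mito_2")
  chl <- makeIcosphere(2, 3, center = c(0, 9, 0), name = "chl")
  sc <- OrganelleScene(list(chl = chl, mito_1 = m1, mito_2 = m2))
  r <- organelleRatios(sc, "chl", "mito")
  expect_equal(r$volume_ratio, 8 / 2, tolerance = 1e-9)
  expect_equal(r$area_ratio, 4 / 2, tolerance = 1e-9)
})

test_that("toy cyst occupancies match the generator's analytic volumes within 3%", {
  sc <- defaultToyCyst()
  gt <- sc@metadata$groundTruth
  rep <- occupancyReport(sc)
  Vcell <- rep@provenance$cell_volume_um3 * 1e9
  gt$class <- sub("_[0-9]+$", "", gt$name)
  for (i in seq_len(nrow(rep@perOrganelle))) {
    cl <- rep@perOrganelle$name[i]
    want <- sum(gt$volume_nm3[gt$class == cl]) / gt$volume_nm3[gt$name == "cell"]
    expect_lt(abs(rep@perOrganelle$occupancy[i] - want) / want, 0.03)
  }
})

test_that("the pyrenoid holds its configured share of the chloroplast volume", {
  sc <- defaultToyCyst()
  r <- organelleRatios(sc, "pyrenoid", "chloroplast")
  expect_lt(abs(r$volume_ratio - 0.05) / 0.05, 0.03)
})

test_that("assembleReport covers the default pairs and serializes deterministically", {
  sc <- smallToyCyst()
  rep <- assembleReport(sc)
  expect_true(all(c("chloroplast->mitochondrion", "mitochondrion->chloroplast",
                    "chloroplast->LD", "mitochondrion->starch") %in%
                    names(rep@proximity)))
  expect_gte(nrow(rep@ratios), 1L)
  js1 <- reportJSON(rep)
  js2 <- reportJSON(assembleReport(sc))
  expect_identical(js1, js2)
  parsed <- jsonlite::fromJSON(js1)
  expect_identical(parsed$schema, "cystmorph-report/1")
  expect_true(all(c("per_organelle", "ratios", "proximity", "provenance")
                  %in% names(parsed)))
})

test_that("pairs naming absent organelles are skipped with a warning, not an error", {
  sc <- makeTwoSphereScene(1, 1, 3, subdivisions = 3)
  sc@cellBoundary <- makeIcosphere(10, 3, center = c(1.5, 0, 0), name = "cell")
  expect_warning(rep <- assembleReport(sc,
                                       ratioPairs = list(c("A", "B")),
                                       proximityPairs = list(c("A", "starch"))),
                 "starch")
  expect_identical(length(rep@proximity), 0L)
  expect_identical(nrow(rep@ratios), 1L)
})
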