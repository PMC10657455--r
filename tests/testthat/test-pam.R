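test_that("PAM parameters follow the pulse formulas", {
  p <- suppressWarnings(
    pamParameters(F = 300, Fm_prime = 600, I = 337, F0 = 240, Fm = 500))
  expect_equal(p$Y_II, 0.5)
  expect_equal(p$rETR, 168.5)
  expect_equal(p$Fv_Fm, 0.52)
  # Fm' above the dark Fm is a data-quality condition, reported as computed
  expect_warning(pamParameters(300, 600, 337, 240, 500), "negative NPQ")
  expect_equal(suppressWarnings(
    pamParameters(300, 600, 337, 240, 500)$NPQ), (500 - 600) / 600)

  q <- pamParameters(F = 350, Fm_prime = 450, I = 100, F0 = 240, Fm = 500)
  expect_equal(q$NPQ, (500 - 450) / 450)
  expect_equal(q$Y_II + 350 / 450, 1)             # Y(II) + F/Fm' = 1
  r <- pamParameters(F = 450, Fm_prime = 450, I = 100, F0 = 240, Fm = 500)
  expect_identical(r$Y_II, 0)
  expect_identical(r$rETR, 0)
  s <- pamParameters(F = 300, Fm_prime = 500, I = 0, F0 = 240, Fm = 500)
  expect_identical(s$NPQ, 0)
})

test_that("degenerate PAM inputs are clamped or rejected", {
  expect_warning(p <- pamParameters(F = 470, Fm_prime = 450, I = 50,
                                    F0 = 240, Fm = 500), "clamped")
  expect_identical(p$Y_II, 0)
  expect_error(pamParameters(-1, 450, 50, 240, 500), "positive")
  expect_error(pamParameters(300, 450, 50, 500, 240), "Fm >= F0")
})

test_that("rETR is exactly linear in irradiance at fixed yields", {
  Is <- c(0, 22, 100, 337, 1000)
  vals <- vapply(Is, function(I)
    pamParameters(F = 300, Fm_prime = 450, I = I, F0 = 240, Fm = 500)$rETR,
    numeric(1))
  Y <- (450 - 300) / 450
  expect_identical(vals, Y * Is)
})

test_that("protocol summaries average per phase and enforce phase order", {
  rec <- data.frame(time = 1:8 * 30,
                    phase = rep(c("D", "L1", "L2", "D2"), each = 2),
                    F = 300, Fm_prime = 450,
                    I = rep(c(0, 22, 337, 0), each = 2))
  tr <- PAMTrace(rec, F0 = 240, Fm = 500)
  sm <- protocolSummary(tr)
  expect_identical(sm$phase, c("D", "L1", "L2", "D2"))
  Y <- (450 - 300) / 450
  expect_equal(sm$Y_II, rep(Y, 4))
  expect_equal(sm$rETR, Y * c(0, 22, 337, 0))
  expect_equal(sm$Fv_Fm, rep(0.52, 4))

  expect_error(protocolSummary(PAMTrace(rec[rec$phase != "L2", ],
                                        F0 = 240, Fm = 500)), "missing")
  shuffled <- PAMTrace(rec[c(3:4, 1:2, 5:8), ], F0 = 240, Fm = 500)
  expect_error(protocolSummary(shuffled), "order")
})

test_that("the synthetic trace saturates: Y(II) drops and NPQ rises at high light", {
  tr <- makePamTrace(seed = 11L)
  sm <- protocolSummary(tr)
  expect_lt(sm$Y_II[sm$phase == "L2"], sm$Y_II[sm$phase == "L1"])
  expect_gt(sm$NPQ[sm$phase == "L2"], sm$NPQ[sm$phase == "L1"])
  expect_gt(sm$rETR[sm$phase == "L2"], sm$rETR[sm$phase == "L1"])
})

test_that("PAM traces round-trip through the CSV dialect", {
  tr <- makePamTrace(seed = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  writePamTrace(tr, f)
  back <- readPamTrace(f)
  expect_equal(back@F0, tr@F0)
  expect_equal(back@Fm, tr@Fm)
  expect_equal(back@records$F, tr@records$F, tolerance = 1e-9)
  expect_identical(back@records$phase, tr@records$phase)
})

test_that("liquid-phase renormalisation divides by LWC and pre-concentration", {
  expect_equal(liquidPhaseConcentration(1.5e-6, lwc = 0.15), 1e-5)
  expect_equal(liquidPhaseConcentration(5, lwc = 1), 5)
  expect_equal(liquidPhaseConcentration(12, lwc = 0.15,
                                        concentrationFactor = 12), 12 / 12 / 0.15)
  # homogeneous of degree 1 in the meltwater concentration
  x <- c(0.1, 1, 10)
  expect_equal(liquidPhaseConcentration(3 * x, lwc = 0.2),
               3 * liquidPhaseConcentration(x, lwc = 0.2))
  expect_error(liquidPhaseConcentration(1, lwc = 0), "lwc")
  expect_error(liquidPhaseConcentration(1, lwc = 1.2), "lwc")
  expect_error(liquidPhaseConcentration(-1), "non-negative")
})
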