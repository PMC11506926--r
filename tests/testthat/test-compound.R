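test_that("fraction ionized follows Henderson-Hasselbalch", {
  expect_equal(fraction_ionized(12.22, 7.4, "monoprotic base"),
               1 / (1 + 10^(7.4 - 12.22)), tolerance = 1e-12)
  expect_equal(round(fraction_ionized(12.22, 7.4, "monoprotic base"), 6),
               0.999985)
  expect_equal(fraction_ionized(7.4, 7.4, "monoprotic base"), 0.5)
  expect_equal(fraction_ionized(4.5, 4.5, "monoprotic acid"), 0.5)
  expect_identical(fraction_ionized(9, 7.4, "neutral"), 0)
  expect_error(fraction_ionized(9, 7.4, "zwitterion"), "unsupported")
  # monotone in (ph - pka), with opposite signs for acid and base
  ph <- seq(2, 12, 0.5)
  fb <- fraction_ionized(7, ph, "monoprotic base")
  fa <- fraction_ionized(7, ph, "monoprotic acid")
  expect_true(all(diff(fb) < 0))
  expect_true(all(diff(fa) > 0))
})

test_that("blood unbound fraction is fu_plasma / BP, clamped at 1", {
  expect_equal(round(blood_unbound_fraction(0.03, 0.63), 4), 0.0476)
  expect_identical(blood_unbound_fraction(1, 1), 1)
  expect_warning(out <- blood_unbound_fraction(0.5, 0.25), "clamp")
  expect_identical(out, 1)
  expect_error(blood_unbound_fraction(0.1, 0), "positive")
})

test_that("blood-cell partition coefficient from B/P, fu and hematocrit", {
  expect_equal(round(kpu_blood_cells(0.63, 0.03, 0.45), 2), 5.93)
  expect_equal(kpu_blood_cells(1, 1, 0.45), 1)
  expect_warning(out <- kpu_blood_cells(0.55, 0.03, 0.45), "no blood-cell")
  expect_identical(out, 0)
})

test_that("ka from Peff: cylinder mapping with unit conversion", {
  ka <- ka_from_peff(5.13, 1.75)
  expect_equal(ka, 2 * (5.13e-4 * 3600) / 1.75, tolerance = 1e-12)
  expect_equal(round(ka, 2), 2.11)
  expect_equal(ka_from_peff(2 * 5.13, 1.75), 2 * ka)
  expect_equal(ka_from_peff(5.13, 3.5), ka / 2)
  expect_error(ka_from_peff(0, 1.75), "positive")
})

test_that("Qgut hybrid flow is symmetric and bounded by its arguments", {
  expect_equal(qgut_hybrid(18, 18), 9)
  expect_identical(qgut_hybrid(0, 18), 0)
  expect_equal(qgut_hybrid(1e9, 18), 18, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50)
    expect_equal(qgut_hybrid(a, b), qgut_hybrid(b, a))
    expect_lte(qgut_hybrid(a, b), min(a, b))
  }
  expect_error(qgut_hybrid(5, 0), "positive")
})

test_that("compound invariants are enforced", {
  expect_error(compound_params("x", mw = 300, bp_ratio = 1, fu_plasma = 1.2,
                               vss = 1), "fu_plasma")
  expect_error(compound_params("x", mw = 300, bp_ratio = 1, fu_plasma = 0.1,
                               vss = 1, kinact = 0.5, kapp = 0), "kapp")
  expect_error(compound_params("x", mw = 300, bp_ratio = 1, fu_plasma = 0.1,
                               vss = 1, fm_cyp3a4 = 1.5), "fm_cyp3a4")
  expect_error(compound_params("x", mw = 300, bp_ratio = 1, fu_plasma = 0.1,
                               vss = 1, compound_type = "diprotic"),
               "compound_type")
})

test_that("piperine parameter set carries the model inputs", {
  p <- pip()
  expect_s3_class(p, "compound_params")
  expect_equal(p$mw, 285.34)
  expect_equal(p$pka, 12.22)
  expect_equal(p$bp_ratio, 0.63)
  expect_equal(p$fu_plasma, 0.03)
  expect_equal(p$qgut, 15.4)
  expect_equal(p$vss, 0.826)
  expect_equal(p$clint_hlm, 24.2)
  expect_equal(p$kapp, 6.74)
  expect_equal(p$kinact, 0.558)
  expect_equal(p$fu_mic, 0.863)
})

test_that("compound files round-trip and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_compound_params(pip(), f)
  p2 <- read_compound_params(f)
  num <- names(pip())[vapply(pip(), is.numeric, logical(1))]
  for (nm in num) expect_equal(p2[[nm]], pip()[[nm]], label = nm)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: x", "mw: 100", "bp_ratio: 1", "fu_plasma: 0.1",
               "vss: 1", "melting_point: 400"), f2)
  expect_error(read_compound_params(f2), "melting_point")
  expect_error(read_compound_params(f2), "accepted keys")
})
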