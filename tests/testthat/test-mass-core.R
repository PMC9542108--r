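test_that("mz/mass conversions reproduce the printed charge-reduced pairs", {
  expect_equal(mz_from_mass(1000, 1), 1001.007276, tolerance = 1e-9)
  # the complex precursor and its charge-reduced products
  expect_equal(round(mz_from_mass(14675.4, 8)), 1835)
  expect_equal(mz_from_mass(14675.4, 7), 2097.5, tolerance = 0.1 / 2097.5)
  expect_equal(mass_from_mz(1.007276, 1), 0)
  expect_equal(mass_from_mz(2097.5, 7), 14675.45, tolerance = 1e-6)
  expect_equal(mass_from_mz(2446.9, 6), 14675.36, tolerance = 1e-6)
  # pair consistency of the two printed products
  expect_lt(abs(mass_from_mz(2097.5, 7) - mass_from_mz(2446.9, 6)), 0.15)
  expect_error(mz_from_mass(-5, 2), class = "tptcr_invalid_input")
  expect_error(mass_from_mz(0.5, 1), class = "tptcr_invalid_input")
})

test_that("mass <-> mz round trip is exact over the native MS regime", {
  set.seed(42)
  for (i in 1:50) {
    M <- runif(1, 1e2, 1e6)
    z <- sample(1:30, 1)
    expect_equal(mass_from_mz(mz_from_mass(M, z), z), M,
                 tolerance = 1e-9)
  }
})

test_that("molecular masses match element-sum oracles", {
  expect_equal(molecular_mass("H2O"), 18.0106, tolerance = 1e-4)
  # bezafibrate: the 361 Da neutral loss, monoisotopic
  expect_equal(molecular_mass("C19H20ClNO4"), 361.108, tolerance = 1e-3)
  expect_equal(molecular_mass("C19H20ClNO4", "average"), 361.82,
               tolerance = 1e-2)
  expect_error(molecular_mass(""), class = "tptcr_invalid_input")
  expect_error(molecular_mass("Qq3"), class = "tptcr_invalid_input")
  counts <- parse_formula("C19H20ClNO4")
  expect_identical(counts[["C"]], 19L)
  expect_identical(counts[["Cl"]], 1L)
  expect_identical(counts[["N"]], 1L)
})

test_that("element mass table covers the required elements, all positive", {
  tab <- element_masses()
  expect_true(all(c("C", "H", "N", "O", "S", "Cl", "Na", "K", "Fe")
                  %in% tab$element))
  expect_true(all(tab$monoisotopic > 0) && all(tab$average > 0))
})

test_that("charge inference solves both printed product pairs", {
  expect_identical(infer_charge_pair(2097.5, 2446.9),
                   c(z_low_mz = 7L, z_high_mz = 6L))
  expect_identical(infer_charge_pair(2259.9, 2636.3),
                   c(z_low_mz = 7L, z_high_mz = 6L))
})

test_that("charge inference rejects degenerate and ambiguous pairs", {
  # a pair whose only integer solution is (1, 0): charge zero is invalid
  expect_error(infer_charge_pair(500, 5000), class = "tptcr_invalid_input")
  # the 1+ peak of M = 1000 next to its apparent "0+" position is instead
  # read as the 2+/1+ pair of a doubled mass - never as charge zero
  expect_identical(unname(infer_charge_pair(1001.00728, 2001.00728)),
                   c(2L, 1L))
  # spacing below the configurable minimum
  expect_error(infer_charge_pair(1000, 1000.5, min_spacing = 1),
               class = "tptcr_ambiguous_charge")
  # real-valued charge exactly between integers
  expect_error(infer_charge_pair(PROTON + 3.5 * 400, PROTON + 3.5 * 400 + 400),
               class = "tptcr_ambiguous_charge")
})

test_that("charge inference is exact on noiseless adjacent pairs", {
  for (M in c(5e3, 1e4, 1.5e4, 2e4)) {
    for (z in 3:25) {
      lad <- exact_ladder(M, c(z, z - 1L))
      got <- infer_charge_pair(lad$mz[1], lad$mz[2])
      expect_identical(unname(got), c(z, z - 1L))
    }
  }
})

test_that("predicted reduction ladders hit the printed values and stay monotone", {
  lad <- predict_reduced_ladder(1835.43, 8, 2)
  expect_equal(lad$z, c(7L, 6L))
  expect_equal(lad$mz, c(2097.5, 2446.9), tolerance = 0.1 / 2097.5)
  full <- predict_reduced_ladder(1835.43, 8, 7)
  expect_identical(nrow(full), 7L)
  expect_identical(full$z[7], 1L)
  expect_true(all(diff(full$mz) > 0))
  expect_error(predict_reduced_ladder(1835.43, 8, 8),
               class = "tptcr_invalid_input")
  # monotonicity across random precursors
  set.seed(7)
  for (i in 1:20) {
    z <- sample(3:25, 1)
    lad <- predict_reduced_ladder(runif(1, 800, 1990), z, z - 1L)
    expect_true(all(diff(lad$mz) > 0))
    expect_true(all(diff(lad$z) == -1L))
  }
})

test_that("noiseless ladder members deconvolve to identical masses", {
  lad <- exact_ladder(12345.6, 9:4)
  masses <- mass_from_mz(lad$mz, lad$z)
  expect_equal(max(masses) - min(masses), 0, tolerance = 1e-9)
})

test_that("charge ladder constructor enforces its invariants", {
  expect_error(new_charge_ladder(tibble::tibble(mz = c(1000, 1100),
                                                z = c(5L, 5L))),
               class = "tptcr_invalid_input")
  expect_error(new_charge_ladder(tibble::tibble(mz = numeric(),
                                                z = integer())),
               class = "tptcr_invalid_input")
  lad <- new_charge_ladder(tibble::tibble(mz = c(2446.9, 2097.5),
                                          z = c(6L, 7L)))
  expect_identical(lad$z, c(7L, 6L)) # re-sorted by m/z
  expect_identical(attr(lad, "provenance"), "observed")
})
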