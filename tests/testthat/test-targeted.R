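test_that("target tables reproduce the printed product pairs", {
  tab <- build_target_table(liver_mixture(), n_reduced = 2)
  cx <- tab[tab$species == "FABP1+bezafibrate", ]
  expect_equal(cx$product_mz[[1]], c(2097.5, 2446.9),
               tolerance = 0.1 / 2097.5)
  expect_identical(cx$product_z[[1]], c(7L, 6L))
  gl <- tab[tab$species == "alpha-globin+heme", ]
  expect_equal(gl$product_mz[[1]], c(2259.9, 2636.4),
               tolerance = 0.1 / 2259.9)
  expect_true(all(tab$precursor_mz < 2000))
})

test_that("precursors above the quadrupole isolation limit are rejected by name", {
  sp <- dplyr::bind_rows(
    species_definition("ok", 14675.4, 8),
    species_definition("too-big", 20000, 8))
  sp$precursor_z <- c(8L, 8L)
  err <- expect_error(build_target_table(sp),
                      class = "tptcr_isolation_limit")
  expect_match(conditionMessage(err), "too-big")
  # overridable for hypothetical hardware
  tab <- build_target_table(sp, isolation_limit = 8000)
  expect_identical(nrow(tab), 2L)
})

test_that("window extraction integrates a lone peak to its centroid intensity", {
  cfg <- acquisition_config(mz_range = c(2080, 2120), resolving_power = 1000,
                            noise_sd = 0, shot_cv = 0)
  sp <- render_profile(tibble::tibble(mz = 2097.5, intensity = 2.5), cfg)
  expect_equal(extract_window(sp, 2097.5, half_width = 5), 2.5,
               tolerance = 0.02)
  empty <- new_spectrum(numeric(), numeric())
  expect_identical(extract_window(empty, 2097.5, 0.5), 0)
  # overlapping windows are each reported independently
  a <- extract_window(sp, 2097.3, half_width = 1)
  b <- extract_window(sp, 2097.7, half_width = 1)
  expect_gt(a, 0)
  expect_gt(b, 0)
})

test_that("product-ion images match the phantom ground truth", {
  ph <- small_phantom(seed = 12)
  targets <- build_target_table(ph$species)
  img <- product_ion_image(ph, "FABP1+bezafibrate", targets)
  tm <- truth_map(ph, "FABP1+bezafibrate")
  expect_gte(cor(img$intensity, tm$abundance), 0.9)
  img_g <- product_ion_image(ph, "alpha-globin+heme", targets)
  tm_g <- truth_map(ph, "alpha-globin+heme")
  expect_gte(cor(img_g$intensity, tm_g$abundance), 0.9)
  expect_true(all(img$intensity >= 0))
})

test_that("an all-background phantom images to (near) zero", {
  sp <- liver_mixture()
  sp$abundance <- 0
  ph <- generate_phantom(n_rows = 8, n_cols = 8, species = sp, seed = 2,
                         dosed = FALSE,
                         cfg = acquisition_config(
                           mz_range = c(1500, 2900), resolving_power = 1000,
                           noise_sd = 0, shot_cv = 0))
  targets <- build_target_table(sp)
  img <- product_ion_image(ph, "apo-FABP1", targets)
  expect_true(all(img$intensity == 0))
})

test_that("image generation is linear in species abundance", {
  base <- liver_mixture()
  doubled <- base
  doubled$abundance[doubled$name == "ACBP"] <- 2 *
    doubled$abundance[doubled$name == "ACBP"]
  noiseless <- acquisition_config(mz_range = c(1500, 2900),
                                  resolving_power = 1000,
                                  noise_sd = 0, shot_cv = 0)
  ph1 <- generate_phantom(n_rows = 8, n_cols = 8, species = base,
                          seed = 3, cfg = noiseless)
  ph2 <- generate_phantom(n_rows = 8, n_cols = 8, species = doubled,
                          seed = 3, cfg = noiseless)
  targets <- build_target_table(base)
  i1 <- product_ion_image(ph1, "ACBP", targets)
  i2 <- product_ion_image(ph2, "ACBP", targets)
  nz <- i1$intensity > 1e-12
  expect_equal(i2$intensity[nz] / i1$intensity[nz],
               rep(2, sum(nz)), tolerance = 1e-6)
})

test_that("TIC normalisation rescales per pixel without changing support", {
  ph <- small_phantom(seed = 13)
  targets <- build_target_table(ph$species)
  raw <- product_ion_image(ph, "ACBP", targets)
  tic <- product_ion_image(ph, "ACBP", targets, normalize = "tic")
  expect_true(all(tic$intensity >= 0 & tic$intensity <= 1))
  joined <- dplyr::inner_join(tic, ph$pixels, by = c("row", "col"))
  expect_gt(mean(joined$intensity[joined$region == "bulk"]),
            mean(joined$intensity[joined$region == "background"]))
  expect_gt(mean(raw$intensity[ph$pixels$region == "bulk"]), 0)
})

test_that("composites scale channels independently and check dimensions", {
  ph <- small_phantom(seed = 14)
  targets <- build_target_table(ph$species)
  red <- product_ion_image(ph, "alpha-globin+heme", targets)
  blue <- product_ion_image(ph, "FABP1+bezafibrate", targets)
  comp <- composite_image(red, blue)
  expect_true(all(comp$red >= 0 & comp$red <= 1))
  expect_true(all(comp$blue >= 0 & comp$blue <= 1))
  # red dominates in the vessel, blue in bulk (pixel-majority check)
  joined <- dplyr::inner_join(comp, ph$pixels, by = c("row", "col"))
  vessel <- joined[joined$region == "vessel", ]
  bulk <- joined[joined$region == "bulk", ]
  expect_gt(mean(vessel$red > vessel$blue), 0.5)
  expect_gt(mean(bulk$blue > bulk$red), 0.5)
  # identical channels render equal red and blue everywhere
  same <- composite_image(red, red)
  expect_equal(same$red, same$blue)
  # dimension mismatch is an error
  ph2 <- generate_phantom(n_rows = 4, n_cols = 4, seed = 1)
  expect_error(
    composite_image(red, product_ion_image(ph2, "ACBP",
                                           build_target_table(ph2$species))),
    class = "tptcr_invalid_input")
})

test_that("region contrast separates vessel from bulk species", {
  ph <- small_phantom(seed = 15)
  targets <- build_target_table(ph$species)
  img_g <- product_ion_image(ph, "alpha-globin+heme", targets)
  img_c <- product_ion_image(ph, "FABP1+bezafibrate", targets)
  expect_gt(region_contrast(img_g, ph$pixels), 5)
  expect_lt(region_contrast(img_c, ph$pixels), 0.2)
  # uniform image has unit contrast
  uni <- img_g
  uni$intensity <- rep(1, nrow(uni))
  expect_equal(region_contrast(uni, ph$pixels), 1)
  expect_error(region_contrast(img_g, ph$pixels, a = "nonexistent"),
               class = "tptcr_invalid_input")
  # zero-mean denominator reports the +Inf sentinel
  zed <- img_g
  zed$intensity <- ifelse(ph$pixels$region == "vessel", 1, 0)
  expect_identical(region_contrast(zed, ph$pixels), Inf)
})

test_that("a precursor-overlapping interferent does not perturb product images", {
  noiseless <- acquisition_config(mz_range = c(1500, 2900),
                                  resolving_power = 1000,
                                  noise_sd = 0.002, shot_cv = 0)
  clean <- generate_phantom(n_rows = 12, n_cols = 12, seed = 17,
                            cfg = noiseless)
  bg <- tibble::tibble(name = "lipid cluster", mass = 1835.43 - PROTON,
                       z = 1L, abundance = 0.5, region = "bulk")
  dirty <- generate_phantom(n_rows = 12, n_cols = 12, seed = 17,
                            cfg = noiseless, background_species = bg)
  targets <- build_target_table(clean$species)
  i_clean <- product_ion_image(clean, "FABP1+bezafibrate", targets)
  i_dirty <- product_ion_image(dirty, "FABP1+bezafibrate", targets)
  bulk_mean <- mean(i_clean$intensity[clean$pixels$region == "bulk"])
  expect_lt(max(abs(i_dirty$intensity - i_clean$intensity)),
            0.01 * bulk_mean)
})
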