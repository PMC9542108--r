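test_that("charge envelopes are Gaussian-weighted, normalised and peak at z0", {
  sp <- species_definition("complex", 14675.4, z0 = 8, sigma_z = 0.7,
                           abundance = 1)
  pk <- simulate_envelope(sp)
  expect_equal(sum(pk$intensity), 1, tolerance = 1e-9)
  expect_identical(pk$z[which.max(pk$intensity)], 8L)
  expect_equal(pk$mz[pk$z == 8L], 1835.43, tolerance = 0.01 / 1835)
  # delta limit: vanishing width leaves a single charge state
  narrow <- simulate_envelope(
    species_definition("x", 10000, z0 = 6, sigma_z = 1e-9))
  expect_identical(nrow(narrow), 1L)
  expect_identical(narrow$z, 6L)
  # zero abundance yields nothing
  expect_identical(
    nrow(simulate_envelope(species_definition("x", 10000, 6,
                                              abundance = 0))), 0L)
})

test_that("rendered peaks have the configured width and conserve area", {
  cfg <- acquisition_config(mz_range = c(1950, 2050), resolving_power = 1000,
                            noise_sd = 0, shot_cv = 0, baseline = 0)
  sp <- render_profile(tibble::tibble(mz = 2000, intensity = 3), cfg)
  # FWHM = m/z / R = 2.0, measured at interpolated half-height crossings
  half <- max(sp$intensity) / 2
  above <- which(sp$intensity >= half)
  lo <- min(above)
  hi <- max(above)
  x_left <- approx(sp$intensity[(lo - 1):lo], sp$mz[(lo - 1):lo],
                   xout = half)$y
  x_right <- approx(sp$intensity[hi:(hi + 1)], sp$mz[hi:(hi + 1)],
                    xout = half)$y
  expect_equal(x_right - x_left, 2.0, tolerance = 0.02)
  # Riemann integral equals the centroid intensity
  step <- sp$mz[2] - sp$mz[1]
  expect_equal(sum(sp$intensity) * step, 3, tolerance = 0.01)
})

test_that("profile rendering is deterministic under a fixed seed", {
  cfg <- acquisition_config(mz_range = c(1800, 1900), noise_sd = 0.01)
  pk <- tibble::tibble(mz = 1835.4, intensity = 1)
  a <- render_profile(pk, cfg, seed = 99)
  b <- render_profile(pk, cfg, seed = 99)
  expect_identical(a$intensity, b$intensity)
  c <- render_profile(pk, cfg, seed = 100)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("empty peak list with zero baseline renders an all-zero spectrum", {
  cfg <- acquisition_config(mz_range = c(1000, 1100), noise_sd = 0,
                            baseline = 0)
  sp <- render_profile(tibble::tibble(mz = numeric(),
                                      intensity = numeric()), cfg)
  expect_true(all(sp$intensity == 0))
})

test_that("trace complex is invisible in the full scan but detected in SIM", {
  mixture <- liver_mixture(complex_fraction = 0.005)
  cfg <- acquisition_config(mz_range = c(1000, 2100))
  full <- simulate_full_scan(mixture, cfg, seed = 21)
  window <- c(1820, 1850)
  in_window <- full[full$mz >= window[1] & full$mz <= window[2], ]
  pk_full <- centroid(in_window, snr_threshold = 3)
  expect_false(any(abs(pk_full$mz - 1835.4) < 1)) # lost in the noise
  sim <- simulate_sim_scan(mixture, window, cfg, seed = 21)
  pk_sim <- centroid(sim, snr_threshold = 3)
  expect_true(any(abs(pk_sim$mz - 1835.4) < 1)) # rescued by accumulation
  # control tissue: no complex, nothing appears in the window
  ctrl <- simulate_sim_scan(liver_mixture(complex_fraction = 0),
                            window, cfg, seed = 21)
  pk_ctrl <- centroid(ctrl, snr_threshold = 3)
  expect_false(any(abs(pk_ctrl$mz - 1835.4) < 1))
})

test_that("SIM improves SNR by the configured gain", {
  sp1 <- species_definition("x", 14675.4, 8, 0.7, 0.05)
  cfg <- acquisition_config(mz_range = c(1700, 2000), noise_sd = 0.002,
                            shot_cv = 0, sim_gain = 20)
  window <- c(1820, 1850)
  snr_of <- function(s) {
    sub <- s[s$mz >= window[1] & s$mz <= window[2], ]
    (max(sub$intensity) - median(sub$intensity)) / mad(sub$intensity)
  }
  ratios <- vapply(1:50, function(seed) {
    snr_of(simulate_sim_scan(sp1, window, cfg, seed = seed)) /
      snr_of(simulate_full_scan(sp1, cfg, seed = seed))
  }, numeric(1))
  expect_equal(mean(ratios), 20, tolerance = 0.2)
})

test_that("SIM window validation rejects bad windows", {
  cfg <- acquisition_config(mz_range = c(1000, 2000))
  expect_error(simulate_sim_scan(liver_mixture(), c(1900, 1800), cfg),
               class = "tptcr_invalid_input")
  expect_error(simulate_sim_scan(liver_mixture(), c(1900, 2500), cfg),
               class = "tptcr_invalid_input")
})

test_that("PTCR redistributes intensity without creating it", {
  mix <- liver_mixture()
  pre <- tibble::tibble(name = mix$name, mass = mix$mass,
                        z = mix$precursor_z, intensity = c(1, 0.4, 0.3, 0.2))
  out <- simulate_ptcr(pre, 1.5)
  expect_equal(sum(out$intensity), sum(pre$intensity), tolerance = 1e-9)
  # survivor fraction is the Poisson zero class
  surv <- out[out$kind == "survivor" & out$species == "apo-FABP1", ]
  expect_equal(surv$intensity, dpois(0, 1.5), tolerance = 1e-9)
})

test_that("PTCR of the complex puts its top products at the printed m/z", {
  pre <- tibble::tibble(name = "complex", mass = 14675.4, z = 8L,
                        intensity = 1)
  out <- simulate_ptcr(pre, 1.5)
  prod <- out[out$kind == "product", ]
  top2 <- prod[order(-prod$intensity), ][1:2, ]
  expect_equal(sort(top2$mz), c(2097.5, 2446.9), tolerance = 0.1 / 2097.5)
  expect_setequal(top2$z, c(7L, 6L))
})

test_that("PTCR limits: vanishing mu leaves only survivors; 1+ cannot reduce", {
  pre <- tibble::tibble(name = "x", mass = 10000, z = 5L, intensity = 1)
  out <- simulate_ptcr(pre, 1e-12)
  expect_equal(out$intensity[out$kind == "survivor"], 1, tolerance = 1e-6)
  single <- simulate_ptcr(tibble::tibble(name = "y", mass = 1834.4,
                                         z = 1L, intensity = 0.7), 1.5)
  expect_identical(nrow(single), 1L)
  expect_identical(single$kind, "survivor")
  expect_equal(single$intensity, 0.7)
})

test_that("HCD emits the neutral-loss product and no free-ligand ion", {
  cx <- tibble::tibble(name = "complex", mass = 14675.4, z = 8L,
                       intensity = 1)
  ms2 <- simulate_hcd(cx, "C19H20ClNO4", hcd_config(nce = 7))
  prot <- ms2[ms2$kind == "protein", ]
  prec <- ms2[ms2$kind == "precursor", ]
  expect_equal(prot$mz, 1790.3, tolerance = 0.05 / 1790)
  expect_identical(prot$z, 8L) # charge retained by the protein
  expect_equal(prec$mz, 1835.4, tolerance = 0.05 / 1835)
  expect_false(any(abs(ms2$mz - 362.1) < 5)) # ligand leaves neutral
  expect_equal(sum(ms2$intensity), 1, tolerance = 1e-9)
})

test_that("HCD limiting collision energies behave as expected", {
  cx <- tibble::tibble(name = "complex", mass = 14675.4, z = 8L,
                       intensity = 1)
  off <- simulate_hcd(cx, "C19H20ClNO4", hcd_config(nce = 0))
  expect_identical(off$kind, "precursor")
  expect_equal(off$intensity, 1)
  hot <- simulate_hcd(cx, "C19H20ClNO4", hcd_config(nce = 1000))
  expect_false("precursor" %in% hot$kind)
  expect_error(simulate_hcd(tibble::tibble(name = "tiny", mass = 100,
                                           z = 1L, intensity = 1),
                            "C19H20ClNO4"),
               class = "tptcr_invalid_input")
  # p_d monotone non-decreasing in NCE
  nce <- seq(0, 50, by = 5)
  expect_true(all(diff(dissociation_prob(nce)) >= 0))
})
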