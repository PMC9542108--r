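# Independent oracles and fixture builders used across the suite.

PROTON <- 1.007276

# Exhaustive charge assignment for a peak pair assumed to be adjacent
# charge states: enumerate every z and keep those for which the mass
# implied by the lower-m/z peak predicts the higher-m/z peak within tol.
# Independent of find_charge_series / infer_charge_pair.
brute_force_pair_charges <- function(mz_lo, mz_hi, z_max = 30, tol = 0.2) {
  hits <- integer()
  for (z in 2:z_max) {
    mass <- z * (mz_lo - PROTON)
    pred_hi <- (mass + (z - 1) * PROTON) / (z - 1)
    if (abs(pred_hi - mz_hi) <= tol) hits <- c(hits, z)
  }
  hits
}

# Exact (noiseless) charge ladder of a species of mass M over charges zs.
exact_ladder <- function(mass, zs) {
  tibble::tibble(mz = (mass + zs * PROTON) / zs, z = as.integer(zs))
}

# One seeded PTCR detection run of a single species: simulate the
# charge-reduced scan at resolving power R with the additive noise floor
# set so the strongest charge-reduced product peak has the requested
# height SNR, then centroid and deconvolve. Returns the top candidate
# mass (NA if nothing found).
ptcr_recovery_run <- function(seed, mass = 14675.4, z = 8L,
                              mean_transfers = 1.5, snr = 20,
                              resolving_power = 1000) {
  pre <- tibble::tibble(name = "sp", mass = mass, z = z, intensity = 1)
  ptcr <- simulate_ptcr(pre, mean_transfers)
  prod <- ptcr[ptcr$kind == "product", ]
  sd_prod <- prod$mz / resolving_power / (2 * sqrt(2 * log(2)))
  h_max <- max(prod$intensity / (sd_prod * sqrt(2 * pi)))
  cfg <- acquisition_config(
    mz_range = c(min(prod$mz) - 50, min(max(prod$mz) + 50, 4000)),
    resolving_power = resolving_power,
    noise_sd = h_max / snr, shot_cv = 0.02)
  sp <- render_profile(tibble::as_tibble(ptcr), cfg, seed = seed)
  pk <- centroid(sp, snr_threshold = 5)
  cands <- find_charge_series(pk)
  if (nrow(cands) == 0) {
    return(NA_real_)
  }
  cands$mass[1]
}

# Small phantom defaults used where full 64 x 64 resolution is not the
# point of the test.
small_phantom <- function(seed = 1, ...) {
  generate_phantom(n_rows = 16, n_cols = 16, seed = seed, ...)
}
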