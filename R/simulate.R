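# Synthetic native ESI spectra: envelopes, profile rendering, full-scan,
# SIM, PTCR and HCD scans. All randomness is seeded and reproducible.

#' Construct a spectrum
#'
#' A spectrum is a tibble of (mz, intensity) samples, profile or centroid,
#' tagged with a scan type and free-form metadata (seed, window, gain ...).
#'
#' @param mz,intensity Numeric vectors of equal length; `mz` sorted
#'   increasing.
#' @param mode `"profile"` or `"centroid"`.
#' @param scan_type One of `"full"`, `"sim"`, `"ms2"`, `"ptcr"`.
#' @param metadata Named list stored as an attribute.
#' @return Tibble with class `ms_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, mode = c("profile", "centroid"),
                         scan_type = "full", metadata = list()) {
  mode <- match.arg(mode)
  if (length(mz) != length(intensity)) {
    abort_input("`mz` and `intensity` must have equal length.")
  }
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  structure(tibble::tibble(mz = as.numeric(mz),
                           intensity = as.numeric(intensity)),
            mode = mode, scan_type = scan_type, metadata = metadata,
            class = c("ms_spectrum", class(tibble::tibble())))
}

spectrum_mode <- function(spectrum) attr(spectrum, "mode") %||% "profile"

#' Discretise a species' native charge-state envelope into centroid peaks
#'
#' One peak per integer charge z, weighted proportional to
#' exp(-(z - z0)^2 / (2 sigma_z^2)) and normalised so the weights sum to
#' the species' total abundance. Charges are enumerated over z0 +/- 5
#' sigma_z (clamped at z >= 1); in the sigma_z -> 0 limit a single peak at
#' round(z0) remains.
#'
#' @param species One-row species tibble (see [species_definition()]) or a
#'   multi-row mixture; all rows are expanded.
#' @param adduct Charge carrier.
#' @return Centroid peak tibble with columns `species`, `mz`, `z`,
#'   `intensity`.
#' @export
simulate_envelope <- function(species, adduct = "proton") {
  purrr::pmap_dfr(
    species[c("name", "mass", "z0", "sigma_z", "abundance")],
    function(name, mass, z0, sigma_z, abundance) {
      if (abundance == 0) {
        return(tibble::tibble(species = character(), mz = numeric(),
                              z = integer(), intensity = numeric()))
      }
      zs <- seq(max(1L, floor(z0 - 5 * sigma_z)), ceiling(z0 + 5 * sigma_z))
      w <- exp(-(zs - z0)^2 / (2 * sigma_z^2))
      if (sum(w) == 0) { # sigma_z -> 0 numerical limit
        zs <- as.integer(round(z0))
        w <- 1
      }
      keep <- w > 1e-12 * max(w)
      zs <- zs[keep]
      w <- w[keep]
      tibble::tibble(species = name,
                     mz = mz_from_mass(mass, zs, adduct),
                     z = as.integer(zs),
                     intensity = abundance * w / sum(w))
    })
}

#' Render centroid peaks as a profile spectrum
#'
#' Each centroid peak becomes a Gaussian of FWHM = m/z / R whose integral
#' (in m/z units) equals the centroid intensity; peaks are summed on a
#' uniform m/z axis, a constant baseline is added, then seeded noise:
#' multiplicative per-peak shot noise (`shot_cv`) and additive per-sample
#' Gaussian noise (`noise_sd`). Peaks outside the scan range are dropped
#' and counted in the `clipped` metadata field.
#'
#' @param peaks Centroid peak tibble with columns `mz`, `intensity`.
#' @param cfg An [acquisition_config()].
#' @param seed Integer seed (NULL: use current RNG stream).
#' @param gain Intensity multiplier applied to all peaks (SIM accumulation).
#' @param scan_type Scan-type tag for the output.
#' @return Profile `ms_spectrum`.
#' @export
render_profile <- function(peaks, cfg = acquisition_config(), seed = NULL,
                           gain = 1, scan_type = "full") {
  lo <- cfg$mz_range[1]
  hi <- cfg$mz_range[2]
  axis <- seq(lo, hi, by = cfg$mz_step)
  inside <- peaks$mz >= lo & peaks$mz <= hi
  n_clipped <- sum(!inside)
  if (n_clipped > 0) {
    tptcr_log("INFO", sprintf("render_profile: %d peak(s) outside [%g, %g] clipped",
                              n_clipped, lo, hi))
  }
  peaks <- peaks[inside, , drop = FALSE]
  signal <- numeric(length(axis))
  with_seed(seed, {
    amp <- peaks$intensity * gain
    if (cfg$shot_cv > 0 && nrow(peaks) > 0) {
      amp <- amp * pmax(0, 1 + stats::rnorm(nrow(peaks), 0, cfg$shot_cv))
    }
    for (k in seq_len(nrow(peaks))) {
      sd_k <- peaks$mz[k] / cfg$resolving_power / (2 * sqrt(2 * log(2)))
      i0 <- max(1L, ceiling((peaks$mz[k] - 6 * sd_k - lo) / cfg$mz_step) + 1L)
      i1 <- min(length(axis),
                floor((peaks$mz[k] + 6 * sd_k - lo) / cfg$mz_step) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      signal[idx] <- signal[idx] +
        amp[k] * stats::dnorm(axis[idx], peaks$mz[k], sd_k)
    }
    intensity <- signal + cfg$baseline
    if (cfg$noise_sd > 0) {
      intensity <- intensity + stats::rnorm(length(axis), 0, cfg$noise_sd)
    }
    new_spectrum(axis, intensity, mode = "profile", scan_type = scan_type,
                 metadata = list(seed = seed, gain = gain,
                                 clipped = n_clipped,
                                 mz_step = cfg$mz_step,
                                 resolving_power = cfg$resolving_power,
                                 noise_sd = cfg$noise_sd))
  })
}

#' Simulate a full-scan native ESI spectrum of a mixture
#'
#' Superposition of every species' charge-state envelope rendered as a
#' profile scan. Trace species (e.g. a protein-drug complex at a fraction
#' of a percent of the free protein) sit below the noise here; the SIM
#' scan is what recovers them.
#'
#' @param mixture Species mixture tibble (see [liver_mixture()]).
#' @inheritParams render_profile
#' @return Profile `ms_spectrum` with scan type `"full"`.
#' @export
simulate_full_scan <- function(mixture, cfg = acquisition_config(),
                               seed = NULL) {
  render_profile(simulate_envelope(mixture), cfg, seed = seed,
                 scan_type = "full")
}

#' Simulate a selected-ion-monitoring (SIM) scan
#'
#' Acquisition restricted to a narrow m/z window. Modelled as ion
#' accumulation: peak intensities are multiplied by the configured gain g
#' while the additive noise floor is unchanged, so peak SNR improves by
#' the factor g. The profile sampling step is inherited from the full-scan
#' configuration so SIM and full-scan spectra are directly comparable.
#'
#' @param mixture Species mixture tibble.
#' @param window SIM window `c(lo, hi)`, inside the configured scan range.
#' @inheritParams render_profile
#' @return Profile `ms_spectrum` with scan type `"sim"`.
#' @export
simulate_sim_scan <- function(mixture, window, cfg = acquisition_config(),
                              seed = NULL) {
  if (length(window) != 2L || window[1] >= window[2]) {
    abort_input("`window` must be c(lo, hi) with lo < hi.")
  }
  if (window[1] < cfg$mz_range[1] || window[2] > cfg$mz_range[2]) {
    abort_input("SIM window must lie inside the configured scan range.")
  }
  wcfg <- cfg
  wcfg$mz_range <- as.numeric(window)
  sp <- render_profile(simulate_envelope(mixture), wcfg, seed = seed,
                       gain = cfg$sim_gain, scan_type = "sim")
  meta <- attr(sp, "metadata")
  meta$window <- as.numeric(window)
  attr(sp, "metadata") <- meta
  sp
}

# Truncated-Poisson weights of a PTCR precursor of charge z:
# survivor fraction P(k = 0); the remaining intensity is spread over
# k = 1 .. z-1 transfers proportional to the Poisson pmf.
ptcr_weights <- function(z, mu) {
  p0 <- stats::dpois(0, mu)
  if (z <= 1L) {
    return(list(survivor = 1, k = integer(), w = numeric()))
  }
  k <- seq_len(z - 1L)
  pk <- stats::dpois(k, mu)
  if (sum(pk) == 0) { # mu -> 0 limit
    return(list(survivor = 1, k = integer(), w = numeric()))
  }
  list(survivor = p0, k = k, w = (1 - p0) * pk / sum(pk))
}

#' Simulate proton transfer charge reduction of isolated precursors
#'
#' Ion/ion proton transfer moves each precursor cation of charge z to
#' products at charges z - k, k >= 1, at m/z values fixed by the conserved
#' neutral mass. The number of transfers per ion is modelled as Poisson
#' with mean `mean_transfers`, truncated to 1 <= k < z for the product
#' fraction; the expected intensity partition is applied deterministically
#' (shot-to-shot sampling noise belongs to profile rendering). The
#' precursor survives with the Poisson zero-probability; a 1+ precursor
#' cannot be reduced and survives intact. Total intensity is conserved.
#'
#' @param precursors Tibble with columns `name`, `mass`, `z`, `intensity`:
#'   the multiplexed isolation list (one charge state per species).
#' @param mean_transfers Mean number of proton transfers mu (> 0 for any
#'   reduction to occur; >= 0 accepted).
#' @param adduct Charge carrier.
#' @return Centroid `ms_spectrum` with per-peak columns `mz`, `intensity`,
#'   `species`, `z`, `kind` (`"survivor"` or `"product"`).
#' @export
simulate_ptcr <- function(precursors, mean_transfers = 1.5,
                          adduct = "proton") {
  check_number(mean_transfers, "mean_transfers", min = 0)
  need <- c("name", "mass", "z", "intensity")
  if (!all(need %in% names(precursors))) {
    abort_input("`precursors` needs columns name, mass, z, intensity.")
  }
  rows <- purrr::pmap_dfr(precursors[need], function(name, mass, z, intensity) {
    z <- as.integer(z)
    wt <- ptcr_weights(z, mean_transfers)
    out <- tibble::tibble(
      species = name,
      mz = mz_from_mass(mass, z, adduct),
      z = z,
      intensity = intensity * wt$survivor,
      kind = "survivor")
    if (length(wt$k)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        species = name,
        mz = mz_from_mass(mass, z - wt$k, adduct),
        z = z - wt$k,
        intensity = intensity * wt$w,
        kind = "product"))
    }
    out
  })
  rows <- dplyr::arrange(rows, .data$mz)
  structure(rows, mode = "centroid", scan_type = "ptcr",
            metadata = list(mean_transfers = mean_transfers),
            class = c("ms_spectrum", class(tibble::tibble())))
}

#' Simulate collision-induced dissociation of a protein-ligand complex
#'
#' At normalized collision energy NCE a fraction p_d(NCE) of the precursor
#' intensity dissociates. In the neutral-loss pathway (the default) the
#' ligand departs uncharged: the free protein appears at mass
#' M - M_ligand at the same charge as the precursor, and no ion appears
#' at the ligand's own m/z. An optional charged-ligand pathway instead
#' emits [ligand+H]+ and the protein at charge z - 1.
#'
#' @param complex_species One-row tibble with columns `name`, `mass`, `z`,
#'   `intensity` for the isolated complex precursor.
#' @param ligand_formula Molecular formula of the ligand (monoisotopic
#'   mass is used for the loss).
#' @param hcd An [hcd_config()].
#' @param adduct Charge carrier.
#' @return Centroid `ms_spectrum` (scan type `"ms2"`) with columns `mz`,
#'   `intensity`, `species`, `z`, `kind` in
#'   (`"precursor"`, `"protein"`, `"ligand"`).
#' @export
simulate_hcd <- function(complex_species, ligand_formula,
                         hcd = hcd_config(), adduct = "proton") {
  need <- c("name", "mass", "z", "intensity")
  if (!all(need %in% names(complex_species)) || nrow(complex_species) != 1L) {
    abort_input("`complex_species` must be one row with name, mass, z, intensity.")
  }
  m_ligand <- molecular_mass(ligand_formula, "monoisotopic")
  M <- complex_species$mass
  z <- as.integer(complex_species$z)
  I <- complex_species$intensity
  if (m_ligand >= M) {
    abort_input("ligand mass must be below the complex mass.")
  }
  p_d <- dissociation_prob(hcd$nce, hcd$nce_scale)
  f_charged <- hcd$charged_ligand_fraction
  rows <- tibble::tibble(
    species = complex_species$name,
    mz = mz_from_mass(M, z, adduct),
    z = z,
    intensity = I * (1 - p_d),
    kind = "precursor")
  # neutral-loss pathway: same charge retained by the protein
  i_neutral <- I * p_d * (1 - f_charged)
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    species = paste0(complex_species$name, " - ligand"),
    mz = mz_from_mass(M - m_ligand, z, adduct),
    z = z,
    intensity = i_neutral,
    kind = "protein"))
  if (f_charged > 0 && z >= 2L) {
    i_ch <- I * p_d * f_charged
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(species = paste0(complex_species$name, " - ligand"),
                     mz = mz_from_mass(M - m_ligand, z - 1L, adduct),
                     z = z - 1L, intensity = i_ch / 2, kind = "protein"),
      tibble::tibble(species = "ligand",
                     mz = m_ligand + adduct_mass(adduct),
                     z = 1L, intensity = i_ch / 2, kind = "ligand"))
  }
  rows <- dplyr::arrange(rows[rows$intensity > 0, ], .data$mz)
  structure(rows, mode = "centroid", scan_type = "ms2",
            metadata = list(nce = hcd$nce, p_d = p_d,
                            ligand_mass = m_ligand),
            class = c("ms_spectrum", class(tibble::tibble())))
}
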