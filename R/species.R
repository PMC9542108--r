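# Species definitions and acquisition / fragmentation configuration.

#' Define an electrosprayed species
#'
#' A species is a neutral molecule with a native charge-state envelope:
#' intensity spread over integer charges around a centre charge `z0` with
#' Gaussian width `sigma_z`. Folded proteins sprayed from non-denaturing
#' buffer carry few charges in a narrow envelope, which is what makes the
#' 8+ state of a ~14.7 kDa complex dominant.
#'
#' @param name Species label.
#' @param mass Neutral mass in Da (> 0). Average-mass centroid for proteins
#'   at low resolving power.
#' @param z0 Envelope centre charge (>= 1; may be non-integer).
#' @param sigma_z Envelope width in charge units (> 0).
#' @param abundance Total abundance (arbitrary units, >= 0).
#' @param region For imaging phantoms: `"bulk"`, `"vessel"` or
#'   `"background"`; where the species lives in tissue.
#' @return One-row tibble; rows can be bound into a mixture table.
#' @export
species_definition <- function(name, mass, z0, sigma_z = 0.7, abundance = 1,
                               region = "bulk") {
  check_number(mass, "mass", positive = TRUE)
  check_number(z0, "z0", min = 1)
  check_number(sigma_z, "sigma_z", positive = TRUE)
  check_number(abundance, "abundance", min = 0)
  tibble::tibble(name = as.character(name), mass = mass, z0 = z0,
                 sigma_z = sigma_z, abundance = abundance,
                 region = region)
}

#' Default liver-like native protein mixture
#'
#' The four species of the targeted liver workflow: apo liver fatty acid
#' binding protein (FABP1), its 1:1 bezafibrate complex (+361.1 Da), the
#' heme-bound alpha-globin monomer (a vasculature marker), and acyl-CoA
#' binding protein (ACBP). Protein masses are the low-resolution centroid
#' values consistent with the charge-reduced ladders the workflow targets;
#' the ACBP mass is a nominal ~10 kDa value for a small cytosolic protein.
#'
#' Abundances are relative to apo-FABP1 = 1. The complex is a trace
#' species: `complex_fraction` (default 0.005) of apo-FABP1, low enough
#' that it sits below the noise in a full scan and is only recovered by
#' SIM accumulation — the regime the targeted workflow is designed for.
#'
#' @param complex_fraction Abundance of the protein-drug complex relative
#'   to apo-FABP1. Set to 0 for a control (undosed) mixture.
#' @return Mixture tibble (one species per row), columns as in
#'   [species_definition()] plus `precursor_z`, the charge state isolated
#'   for targeted PTCR.
#' @export
liver_mixture <- function(complex_fraction = 0.005) {
  check_number(complex_fraction, "complex_fraction", min = 0)
  dplyr::bind_rows(
    species_definition("apo-FABP1", 14314.3, 8, 0.7, 1, "bulk"),
    species_definition("FABP1+bezafibrate", 14675.4, 8, 0.7,
                       complex_fraction, "bulk"),
    species_definition("alpha-globin+heme", 15812.2, 8, 0.7, 0.3, "vessel"),
    species_definition("ACBP", 9938.0, 6, 0.6, 0.4, "bulk")
  ) |>
    dplyr::mutate(precursor_z = as.integer(round(.data$z0)))
}

#' Acquisition configuration
#'
#' Instrument-side parameters of the simulator: scan range, resolving
#' power (FWHM = m/z / R, constant-R peak model), baseline offset,
#' per-sample Gaussian noise, multiplicative shot noise on peak
#' amplitudes, and the SIM intensity gain g.
#'
#' SIM is modelled as ion accumulation: restricting the scan to a narrow
#' window lets low-abundance ions accumulate, multiplying peak intensity
#' by `sim_gain` while the electronic noise floor is unchanged — so the
#' signal-to-noise ratio improves by the same factor g.
#'
#' @param mz_range Scan range `c(lo, hi)`.
#' @param resolving_power R (> 0); FWHM at m/z m is m / R.
#' @param baseline Constant baseline level.
#' @param noise_sd Per-sample additive Gaussian noise sd.
#' @param shot_cv Coefficient of variation of multiplicative per-peak
#'   amplitude noise (0 disables).
#' @param sim_gain SIM accumulation gain g (>= 1).
#' @param mz_step Profile sampling step; default one fifth of the
#'   narrowest FWHM in range.
#' @return A list with class `acquisition_config`.
#' @export
acquisition_config <- function(mz_range = c(500, 4000),
                               resolving_power = 1000,
                               baseline = 0, noise_sd = 0.002,
                               shot_cv = 0.02, sim_gain = 20,
                               mz_step = NULL) {
  if (length(mz_range) != 2L || mz_range[1] >= mz_range[2]) {
    abort_input("`mz_range` must be c(lo, hi) with lo < hi.")
  }
  check_number(resolving_power, "resolving_power", positive = TRUE)
  check_number(sim_gain, "sim_gain", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(shot_cv, "shot_cv", min = 0)
  step <- mz_step %||% (mz_range[1] / resolving_power / 5)
  check_number(step, "mz_step", positive = TRUE)
  structure(list(mz_range = as.numeric(mz_range),
                 resolving_power = resolving_power,
                 baseline = baseline, noise_sd = noise_sd,
                 shot_cv = shot_cv, sim_gain = sim_gain, mz_step = step),
            class = "acquisition_config")
}

#' Collisional activation configuration
#'
#' Higher-energy collisional dissociation (HCD) of the protein-ligand
#' complex is summarised by a dissociation probability p_d as a monotone
#' saturating function of normalized collision energy (NCE):
#' p_d(NCE) = 1 - exp(-NCE / nce_scale). At the 7 % NCE used for the
#' complex this gives substantial but incomplete dissociation.
#'
#' The observed dissociation pathway is neutral ligand loss: the ligand
#' departs uncharged and the free protein retains the precursor charge.
#' A charged-ligand pathway (ligand leaving as [L+H]+, protein at z - 1)
#' is available via `charged_ligand_fraction` but is off by default.
#'
#' @param nce Normalized collision energy in percent (>= 0).
#' @param nce_scale Exponential scale of the dissociation curve, percent.
#' @param charged_ligand_fraction Fraction of dissociation events that
#'   follow the charged-ligand pathway (default 0: purely neutral loss).
#' @return A list with class `hcd_config`.
#' @export
hcd_config <- function(nce = 7, nce_scale = 5, charged_ligand_fraction = 0) {
  check_number(nce, "nce", min = 0)
  check_number(nce_scale, "nce_scale", positive = TRUE)
  check_number(charged_ligand_fraction, "charged_ligand_fraction", min = 0)
  if (charged_ligand_fraction > 1) {
    abort_input("`charged_ligand_fraction` must be in [0, 1].")
  }
  structure(list(nce = nce, nce_scale = nce_scale,
                 charged_ligand_fraction = charged_ligand_fraction),
            class = "hcd_config")
}

#' Dissociation probability at a given collision energy
#'
#' @param nce Normalized collision energy, percent.
#' @param nce_scale Exponential scale (see [hcd_config()]).
#' @return p_d in [0, 1], monotone non-decreasing in `nce`.
#' @export
dissociation_prob <- function(nce, nce_scale = 5) {
  check_number(nce, "nce", min = 0)
  1 - exp(-nce / nce_scale)
}
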