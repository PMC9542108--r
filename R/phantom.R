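# Tissue phantom: a pixel grid with vessel / bulk / background regions,
# per-species ground-truth abundance maps, and a per-pixel targeted-PTCR
# profile spectrum. This is the synthetic stand-in for an imaging run on
# a liver section containing a blood vessel.

#' Generate a targeted-PTCR imaging phantom
#'
#' Builds a rectangular pixel grid mimicking a row-major (line-scan)
#' acquisition over a tissue section. The tissue occupies an inscribed
#' ellipse; pixels outside it are background. A circular blood-vessel
#' region sits inside the tissue; the remainder is bulk tissue. Each
#' species lives in its home region (heme-bound alpha-globin in the
#' vessel; FABP1, the drug complex and ACBP in bulk) at its base
#' abundance, modulated per pixel by seeded log-normal texture, with a
#' small leakage fraction into the other region.
#'
#' The protein-drug complex clears exponentially: its abundance is
#' base * 2^(-dose_time / half_life), so a phantom sampled 2 h post-dose
#' carries more complex than one sampled 6 h post-dose.
#'
#' Each pixel's spectrum is the profile rendering of the targeted PTCR
#' scan of the multiplexed precursor list (every species isolated at its
#' `precursor_z`), with seeded per-sample noise. When `dosed = TRUE`,
#' protonated / sodiated / potassiated free drug is added to bulk pixels
#' (rendered only if the scan range reaches that low). Ground-truth maps
#' are returned alongside the spectra.
#'
#' @param n_rows,n_cols Grid dimensions (rows = scan lines).
#' @param pixel_size Pixel edge length in micrometres (metadata only).
#' @param species Species table with columns as [liver_mixture()]
#'   (including `precursor_z` and `region`).
#' @param dose_time Time since dosing, hours (>= 0).
#' @param half_life Drug clearance half-life, hours (default 4.5, the
#'   midpoint of the 4-5 h plasma half-life reported for rats).
#' @param mean_transfers PTCR mean transfer count mu.
#' @param cfg An [acquisition_config()]; default covers the
#'   charge-reduced product region at R = 1000.
#' @param seed Integer seed; fixed seed gives a bit-identical phantom.
#' @param dosed Logical; FALSE gives a control phantom (complex and free
#'   drug absent regardless of the species table).
#' @param drug_formula Molecular formula of the dosed drug (for the free
#'   drug adduct peaks).
#' @param vessel_centre,vessel_radius Vessel disc, in pixel units
#'   (defaults: one third across the grid, radius ~ grid/8).
#' @param texture_cv Log-normal texture coefficient of variation.
#' @param leakage Fraction of a species' base abundance present in its
#'   non-home region.
#' @param background_species Optional tibble (`name`, `mass`, `z`,
#'   `abundance`, `region`) of untargeted interferents that are
#'   co-isolated (e.g. a 1+ background ion overlapping a precursor m/z)
#'   and undergo the same PTCR step.
#' @return A `tissue_phantom`: list with `pixels` (tibble row, col,
#'   region; 0-based, row-major), `truth` (long tibble row, col, species,
#'   abundance), `peaks` (per-peak metadata), `intensities` (pixel x peak
#'   matrix), `mz` (shared profile axis), `spectra` (pixel x sample
#'   matrix), `species`, and `config`.
#' @export
generate_phantom <- function(n_rows = 64, n_cols = 64, pixel_size = 150,
                             species = liver_mixture(),
                             dose_time = 2, half_life = 4.5,
                             mean_transfers = 1.5,
                             cfg = acquisition_config(
                               mz_range = c(1500, 2900),
                               resolving_power = 1000,
                               noise_sd = 0.002, shot_cv = 0),
                             seed = 1, dosed = TRUE,
                             drug_formula = "C19H20ClNO4",
                             vessel_centre = NULL, vessel_radius = NULL,
                             texture_cv = 0.15, leakage = 0.01,
                             background_species = NULL) {
  check_number(n_rows, "n_rows", integerish = TRUE, min = 1)
  check_number(n_cols, "n_cols", integerish = TRUE, min = 1)
  if (dose_time < 0) abort_input("`dose_time` must be >= 0.")
  check_number(half_life, "half_life", positive = TRUE)
  if (!"precursor_z" %in% names(species)) {
    species$precursor_z <- as.integer(round(species$z0))
  }

  # --- regions -------------------------------------------------------
  px <- tidyr::expand_grid(row = seq_len(n_rows) - 1L,
                           col = seq_len(n_cols) - 1L)
  cy <- (n_rows - 1) / 2
  cx <- (n_cols - 1) / 2
  in_tissue <- ((px$row - cy) / (0.48 * n_rows))^2 +
    ((px$col - cx) / (0.48 * n_cols))^2 <= 1
  vc <- vessel_centre %||% c(row = (n_rows - 1) / 3, col = (n_cols - 1) / 3)
  vr <- vessel_radius %||% (min(n_rows, n_cols) / 8)
  in_vessel <- in_tissue &
    (px$row - vc[[1]])^2 + (px$col - vc[[2]])^2 <= vr^2
  px$region <- dplyr::case_when(in_vessel ~ "vessel",
                                in_tissue ~ "bulk",
                                TRUE ~ "background")
  n_px <- nrow(px)

  # --- ground-truth abundance maps -----------------------------------
  decay <- 2^(-dose_time / half_life)
  sp <- species
  is_complex <- grepl("bezafibrate|complex", sp$name, ignore.case = TRUE)
  sp$abundance[is_complex] <- sp$abundance[is_complex] * decay
  if (!dosed) sp$abundance[is_complex] <- 0

  truth_wide <- with_seed(seed, {
    vapply(seq_len(nrow(sp)), function(i) {
      home <- px$region == sp$region[i]
      other <- px$region != sp$region[i] & px$region != "background"
      base <- numeric(n_px)
      base[home] <- sp$abundance[i]
      base[other] <- sp$abundance[i] * leakage
      if (texture_cv > 0) {
        sdlog <- sqrt(log(1 + texture_cv^2))
        base * stats::rlnorm(n_px, -sdlog^2 / 2, sdlog)
      } else {
        base
      }
    }, numeric(n_px))
  })
  colnames(truth_wide) <- sp$name

  # --- per-pixel targeted PTCR peak intensities ----------------------
  # One PTCR partition per species (shared across pixels), scaled by the
  # pixel's abundance: spectra = intensities %*% gaussian basis.
  peak_rows <- purrr::pmap_dfr(
    list(sp$name, sp$mass, sp$precursor_z),
    function(name, mass, z) {
      unit <- simulate_ptcr(tibble::tibble(name = name, mass = mass,
                                           z = as.integer(z), intensity = 1),
                            mean_transfers)
      tibble::as_tibble(unit)[c("species", "mz", "z", "intensity", "kind")]
    })
  if (!is.null(background_species) && nrow(background_species) > 0) {
    bg_unit <- simulate_ptcr(
      tibble::tibble(name = background_species$name,
                     mass = background_species$mass,
                     z = as.integer(background_species$z),
                     intensity = 1),
      mean_transfers)
    peak_rows <- dplyr::bind_rows(peak_rows,
      tibble::as_tibble(bg_unit)[c("species", "mz", "z", "intensity", "kind")])
    bg_wide <- vapply(seq_len(nrow(background_species)), function(i) {
      reg <- background_species$region[i] %||% "bulk"
      ifelse(px$region == reg, background_species$abundance[i], 0)
    }, numeric(n_px))
    colnames(bg_wide) <- background_species$name
    truth_wide <- cbind(truth_wide, bg_wide)
  }
  if (dosed) {
    m_drug <- molecular_mass(drug_formula, "monoisotopic")
    drug_rel <- 0.2 # free drug adduct intensity relative to complex base
    complex_base <- sum(sp$abundance[is_complex])
    adds <- c("proton", "sodium", "potassium")
    peak_rows <- dplyr::bind_rows(peak_rows, tibble::tibble(
      species = "free drug",
      mz = m_drug + unname(vapply(adds, adduct_mass, numeric(1))),
      z = 1L,
      intensity = drug_rel * complex_base * c(1, 0.5, 0.3),
      kind = "adduct"))
    drug_map <- ifelse(px$region == "bulk", 1, 0)
    truth_wide <- cbind(truth_wide, `free drug` = drug_map)
  }
  peak_rows$peak_id <- seq_len(nrow(peak_rows))

  # pixel x peak intensity matrix; multiplexed isolation accumulates ions
  # like a SIM scan, so the configured gain applies to all targeted peaks
  W <- truth_wide[, match(peak_rows$species, colnames(truth_wide)),
                  drop = FALSE] *
    matrix(peak_rows$intensity, n_px, nrow(peak_rows), byrow = TRUE) *
    cfg$sim_gain

  # --- profile rendering on a shared axis (one matrix product) -------
  lo <- cfg$mz_range[1]
  hi <- cfg$mz_range[2]
  axis <- seq(lo, hi, by = cfg$mz_step)
  inside <- peak_rows$mz >= lo & peak_rows$mz <= hi
  basis <- matrix(0, nrow(peak_rows), length(axis))
  for (k in which(inside)) {
    sd_k <- peak_rows$mz[k] / cfg$resolving_power / (2 * sqrt(2 * log(2)))
    j0 <- max(1L, ceiling((peak_rows$mz[k] - 6 * sd_k - lo) / cfg$mz_step) + 1L)
    j1 <- min(length(axis),
              floor((peak_rows$mz[k] + 6 * sd_k - lo) / cfg$mz_step) + 1L)
    if (j0 > j1) next
    basis[k, j0:j1] <- stats::dnorm(axis[j0:j1], peak_rows$mz[k], sd_k)
  }
  spectra <- as.matrix(W) %*% basis + cfg$baseline
  if (cfg$noise_sd > 0) {
    noise <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                       stats::rnorm(length(spectra), 0, cfg$noise_sd))
    spectra <- spectra + matrix(noise, n_px, length(axis))
  }

  truth <- tibble::as_tibble(truth_wide) |>
    dplyr::mutate(row = px$row, col = px$col) |>
    tidyr::pivot_longer(-c("row", "col"), names_to = "species",
                        values_to = "abundance")

  structure(list(
    pixels = px,
    truth = truth,
    peaks = peak_rows,
    intensities = as.matrix(W),
    mz = axis,
    spectra = spectra,
    species = sp,
    config = list(acquisition = cfg, dose_time = dose_time,
                  half_life = half_life, mean_transfers = mean_transfers,
                  seed = seed, dosed = dosed, pixel_size = pixel_size,
                  texture_cv = texture_cv, leakage = leakage,
                  n_rows = n_rows, n_cols = n_cols)
  ), class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<tissue_phantom> %d x %d pixels (%g um), %d species, dose time %g h\n",
    cfg$n_rows, cfg$n_cols, cfg$pixel_size, nrow(x$species), cfg$dose_time))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s=%d", names(table(x$pixels$region)),
                            table(x$pixels$region)), collapse = ", ")))
  cat(sprintf("  axis: %d samples over [%g, %g] m/z; seed %s\n",
              length(x$mz), min(x$mz), max(x$mz),
              format(cfg$seed)))
  invisible(x)
}

#' Ground-truth abundance map of one species
#'
#' @param phantom A `tissue_phantom`.
#' @param species Species name as it appears in `phantom$truth`.
#' @return Tibble (row, col, abundance).
#' @export
truth_map <- function(phantom, species) {
  out <- dplyr::filter(phantom$truth, .data$species == !!species)
  if (nrow(out) == 0) {
    abort_input(sprintf("species '%s' not present in phantom truth", species))
  }
  out[c("row", "col", "abundance")]
}
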