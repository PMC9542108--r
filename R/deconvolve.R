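# Peak picking and low-resolution intact-mass deconvolution from
# charge-reduced ladders. The key idea: at low resolving power isotopes
# are unresolved, but the m/z spacing of consecutive charge states alone
# determines the charges, and with them the neutral mass.

#' Centroid a profile spectrum
#'
#' Local maxima above `snr_threshold` times a robust noise estimate
#' (median absolute deviation about the median level) are refined by an
#' intensity-weighted centroid over the peak's full-width-at-half-maximum
#' window. When the spectrum carries its resolving power (as every
#' simulator-rendered spectrum does), isolated peaks are further refined
#' by a matched Gaussian template fit at the known width, which reaches
#' close to the noise-limited precision bound and is what makes
#' low-resolution ladder deconvolution accurate to fractions of a Da.
#' Maxima whose half-height windows overlap (closer than half a FWHM)
#' are merged into a single centroid and flagged.
#'
#' @param spectrum Profile `ms_spectrum` (>= 3 samples).
#' @param snr_threshold Minimum signal-to-noise ratio (default 3).
#' @return `CentroidPeakList`: tibble with columns `mz`, `intensity`
#'   (baseline-subtracted apex height), `snr`, `merged`, sorted by m/z.
#'   Empty (zero-row) for an all-zero or featureless spectrum.
#' @export
centroid <- function(spectrum, snr_threshold = 3) {
  x <- spectrum$mz
  y <- spectrum$intensity
  empty <- tibble::tibble(mz = numeric(), intensity = numeric(),
                          snr = numeric(), merged = logical())
  if (length(y) < 3L || all(y == 0)) {
    return(empty)
  }
  level <- stats::median(y)
  noise <- stats::mad(y)
  if (noise == 0) {
    # noiseless rendering: any nonzero deviation is signal
    noise <- max(.Machine$double.eps, 1e-12 * max(abs(y - level)))
  }
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  apex <- which(is_max & (y - level) / noise >= snr_threshold)
  if (length(apex) == 0L) {
    return(empty)
  }
  # half-height window boundaries for each apex
  win <- lapply(apex, function(i) {
    half <- level + (y[i] - level) / 2
    lo <- i
    while (lo > 1L && y[lo - 1L] >= half && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- i
    while (hi < n && y[hi + 1L] >= half && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    c(lo, hi)
  })
  # merge apexes whose separation is under half the local FWHM
  fwhm <- vapply(seq_along(apex), function(k) {
    max(x[win[[k]][2]] - x[win[[k]][1]], spectrum$mz[2] - spectrum$mz[1])
  }, numeric(1))
  grp <- integer(length(apex))
  g <- 0L
  for (k in seq_along(apex)) {
    if (k > 1L &&
        (x[apex[k]] - x[apex[k - 1L]]) < (fwhm[k] + fwhm[k - 1L]) / 4) {
      grp[k] <- g
    } else {
      g <- g + 1L
      grp[k] <- g
    }
  }
  rp <- (attr(spectrum, "metadata") %||% list())$resolving_power
  out <- lapply(split(seq_along(apex), grp), function(ks) {
    i0 <- min(vapply(win[ks], `[`, integer(1), 1))
    i1 <- max(vapply(win[ks], `[`, integer(1), 2))
    idx <- i0:i1
    w <- pmax(y[idx] - level, 0)
    apex_i <- apex[ks][which.max(y[apex[ks]])]
    pos <- sum(x[idx] * w) / sum(w)
    merged <- length(ks) > 1L
    if (!is.null(rp)) {
      # peaks wider than the instrumental line width are unresolved
      # composites: flag them and keep the weighted centroid
      expected_fwhm <- x[apex_i] / rp
      measured_fwhm <- interp_fwhm(x, y, win[[ks[1]]],
                                   level + (y[apex_i] - level) / 2)
      if (length(ks) == 1L && measured_fwhm > 1.1 * expected_fwhm) {
        merged <- TRUE
      }
      if (!merged) {
        pos <- refine_template(x, y - level, apex_i, rp)
      }
    }
    tibble::tibble(
      mz = pos,
      intensity = y[apex_i] - level,
      snr = (y[apex_i] - level) / noise,
      merged = merged)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$mz)
}

# Half-height width of a peak with linear interpolation of the two
# half-level crossings; `win` holds the outermost samples at/above half.
interp_fwhm <- function(x, y, win, half) {
  lo <- win[1]
  hi <- win[2]
  x_left <- if (lo > 1L && y[lo - 1L] < half) {
    x[lo - 1L] + (half - y[lo - 1L]) / (y[lo] - y[lo - 1L]) *
      (x[lo] - x[lo - 1L])
  } else {
    x[lo]
  }
  x_right <- if (hi < length(x) && y[hi + 1L] < half) {
    x[hi] + (y[hi] - half) / (y[hi] - y[hi + 1L]) * (x[hi + 1L] - x[hi])
  } else {
    x[hi]
  }
  x_right - x_left
}

# Matched Gaussian template position fit at the known instrumental width:
# amplitude solved linearly, position by 1-d minimisation over +/- 1 sd
# around the apex.
refine_template <- function(x, y, apex_i, resolving_power) {
  sdw <- x[apex_i] / resolving_power / (2 * sqrt(2 * log(2)))
  idx <- which(abs(x - x[apex_i]) <= 2.5 * sdw)
  if (length(idx) < 4L) {
    return(x[apex_i])
  }
  xi <- x[idx]
  yi <- y[idx]
  sse <- function(mu) {
    g <- stats::dnorm(xi, mu, sdw)
    a <- sum(g * yi) / sum(g * g)
    sum((yi - a * g)^2)
  }
  stats::optimize(sse, c(x[apex_i] - sdw, x[apex_i] + sdw))$minimum
}

# Brute-force check that (mz_lo, mz_hi) are consistent with charges
# (z, z - 1); returns the deconvolved mass or NA.
pair_mass <- function(mz_lo, mz_hi, z, mz_tol, adduct = "proton") {
  mass <- mass_from_mz(mz_lo, z, adduct)
  pred_hi <- mz_from_mass(mass, z - 1L, adduct)
  if (abs(pred_hi - mz_hi) <= mz_tol) mass else NA_real_
}

#' Find charge-reduced series among centroided peaks
#'
#' Every ordered peak pair is tried as a candidate adjacent charge pair
#' (z, z - 1); consistent hypotheses are grown greedily in both
#' directions by predicting the next ladder member's m/z and accepting
#' the nearest observed peak within `mz_tol`. Each retained candidate is
#' scored as (number of members) - lambda * (mass spread / mz_tol), so
#' longer, more self-consistent ladders win; overlapping ladders from
#' multiplexed species are all reported.
#'
#' @param peaks Centroid peak tibble (see [centroid()]), >= 2 rows for
#'   any candidate to be found.
#' @param z_max Largest charge considered (default 30; native proteins
#'   under ~100 kDa).
#' @param mz_tol m/z tolerance for ladder membership (default 0.2, the
#'   low-resolution PTCR regime).
#' @param lambda Spread penalty weight in the score.
#' @param adduct Charge carrier.
#' @return Tibble of candidates sorted by decreasing score: columns
#'   `mass`, `spread`, `n_members`, `score`, and list-columns `z`,
#'   `member_mz`, `peak_index`. Zero rows when nothing is consistent.
#' @export
find_charge_series <- function(peaks, z_max = 30, mz_tol = 0.2,
                               lambda = 1, adduct = "proton") {
  p <- adduct_mass(adduct)
  empty <- tibble::tibble(mass = numeric(), spread = numeric(),
                          n_members = integer(), score = numeric(),
                          z = list(), member_mz = list(),
                          peak_index = list())
  if (nrow(peaks) < 2L) {
    return(empty)
  }
  peaks <- dplyr::arrange(tibble::as_tibble(peaks), .data$mz)
  mz <- peaks$mz
  np <- length(mz)
  cands <- list()
  seen <- character()
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      dm <- mz[j] - mz[i]
      if (dm <= 0) next
      z_real <- 1 + (mz[i] - p) / dm
      z <- round(z_real)
      if (z < 2 || z > z_max) next
      if (is.na(pair_mass(mz[i], mz[j], as.integer(z), mz_tol, adduct))) next
      members_idx <- c(i, j)
      members_z <- c(as.integer(z), as.integer(z) - 1L)
      mass0 <- mass_from_mz(mz[i], z, adduct)
      # grow to lower charges (higher m/z)
      repeat {
        z_next <- members_z[length(members_z)] - 1L
        if (z_next < 1L) break
        pred <- mz_from_mass(mass0, z_next, adduct)
        d <- abs(mz - pred)
        cand <- which(d <= mz_tol)
        if (length(cand) == 0L) break
        pick <- cand[which.min(d[cand])]
        if (pick %in% members_idx) break
        members_idx <- c(members_idx, pick)
        members_z <- c(members_z, z_next)
      }
      # grow to higher charges (lower m/z)
      repeat {
        z_next <- members_z[1L] + 1L
        if (z_next > z_max) break
        pred <- mz_from_mass(mass0, z_next, adduct)
        d <- abs(mz - pred)
        cand <- which(d <= mz_tol)
        if (length(cand) == 0L) break
        pick <- cand[which.min(d[cand])]
        if (pick %in% members_idx) break
        members_idx <- c(pick, members_idx)
        members_z <- c(z_next, members_z)
      }
      o <- order(members_z, decreasing = TRUE)
      members_idx <- members_idx[o]
      members_z <- members_z[o]
      key <- paste(members_idx, members_z, sep = ":", collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      ladder <- new_charge_ladder(
        tibble::tibble(mz = mz[members_idx], z = members_z), "observed")
      dec <- deconvolve_mass(ladder, adduct = adduct)
      cands[[length(cands) + 1L]] <- tibble::tibble(
        mass = dec$mass, spread = dec$spread,
        n_members = length(members_idx),
        score = length(members_idx) - lambda * dec$spread / mz_tol,
        z = list(members_z), member_mz = list(mz[members_idx]),
        peak_index = list(members_idx))
    }
  }
  if (length(cands) == 0L) {
    return(empty)
  }
  dplyr::arrange(dplyr::bind_rows(cands), dplyr::desc(.data$score))
}

#' Deconvolve a neutral mass from a charge ladder
#'
#' Each ladder member independently gives a mass z * (m/z - p); the
#' reported mass is their unweighted mean (product-ion intensities
#' reflect charge-reduction kinetics, not mass accuracy, so members are
#' not intensity-weighted) and the spread is the max - min disagreement,
#' a built-in self-consistency measure.
#'
#' @param ladder A charge ladder (tibble with `mz`, `z`; >= 2 rows).
#' @param adduct Charge carrier.
#' @return One-row tibble: `mass` (Da), `spread` (Da), `n_members`.
#' @examples
#' deconvolve_mass(tibble::tibble(mz = c(2097.5, 2446.9), z = c(7, 6)))
#' @export
deconvolve_mass <- function(ladder, adduct = "proton") {
  if (nrow(ladder) < 2L) {
    rlang::abort("a reported mass needs a ladder with >= 2 members",
                 class = c("tptcr_insufficient_evidence", "tptcr_error"))
  }
  masses <- mass_from_mz(ladder$mz, ladder$z, adduct)
  tibble::tibble(mass = mean(masses), spread = max(masses) - min(masses),
                 n_members = nrow(ladder))
}

#' Match a deconvolved mass against a species table
#'
#' Nearest-mass lookup within `mass_tol`; ties (equal |delta| within
#' numerical precision) are broken alphabetically by name and flagged.
#' No match is a value, not an error.
#'
#' @param mass Deconvolved neutral mass (Da).
#' @param species_table Tibble with columns `name` and `mass`.
#' @param mass_tol Maximum |delta mass| accepted (Da).
#' @return One-row tibble `species`, `species_mass`, `delta`, `tie`;
#'   `species` is `NA` when nothing is within tolerance.
#' @export
match_species <- function(mass, species_table, mass_tol = 2) {
  check_number(mass, "mass", positive = TRUE)
  if (!all(c("name", "mass") %in% names(species_table)) ||
      nrow(species_table) == 0L) {
    abort_input("`species_table` must be non-empty with columns name, mass.")
  }
  delta <- mass - species_table$mass
  ok <- abs(delta) <= mass_tol
  if (!any(ok)) {
    return(tibble::tibble(species = NA_character_,
                          species_mass = NA_real_, delta = NA_real_,
                          tie = FALSE))
  }
  cand <- species_table[ok, ]
  cand$delta <- delta[ok]
  best <- min(abs(cand$delta))
  tied <- abs(abs(cand$delta) - best) <= 1e-9
  tie <- sum(tied) > 1L
  cand <- cand[tied, ]
  cand <- cand[order(cand$name), ][1, ]
  tibble::tibble(species = cand$name, species_mass = cand$mass,
                 delta = cand$delta, tie = tie)
}
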