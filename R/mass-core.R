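# Charge-state arithmetic and molecular mass computation.
#
# All m/z arithmetic uses the charge-carrier (cation) mass, the native-MS
# convention: m/z = (M + z * m_adduct) / z. The electron mass is neglected,
# a < 0.01 Da-per-charge approximation at the low resolving powers targeted
# here.

#' Mass of a charge-carrying adduct cation
#'
#' Cation masses used throughout the package: a bare proton for protonated
#' species, and the sodium / potassium cations for alkali adducts of small
#' molecules. Values are the neutral atom monoisotopic masses minus one
#' electron mass, rounded to the precision conventional in native MS
#' (proton fixed at 1.007276 Da).
#'
#' @param adduct One of `"proton"`, `"sodium"`, `"potassium"`.
#' @return Cation mass in Da (numeric scalar).
#' @examples
#' adduct_mass("proton")
#' @export
adduct_mass <- function(adduct = c("proton", "sodium", "potassium")) {
  adduct <- match.arg(adduct)
  c(proton = 1.007276, sodium = 22.989218, potassium = 38.963158)[[adduct]]
}

.proton <- 1.007276

#' Element mass table
#'
#' Monoisotopic and average atomic masses for the elements handled by the
#' formula parser. Shipped as a plain-text table under
#' `inst/extdata/element_masses.csv`; an alternative table with the same
#' columns can be supplied to override it (e.g. for isotope labelling).
#'
#' @param path Optional path to a CSV with columns
#'   `element, monoisotopic, average`; defaults to the shipped table.
#' @return A tibble with columns `element`, `monoisotopic`, `average`.
#' @export
element_masses <- function(path = NULL) {
  path <- path %||% system.file("extdata", "element_masses.csv",
                                package = "tptcr", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("element", "monoisotopic", "average") %in% names(tab)))
  if (any(tab$monoisotopic <= 0) || any(tab$average <= 0)) {
    abort_input("element masses must all be > 0")
  }
  tab
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas such as `"C19H20ClNO4"` (element symbols are
#' one capital optionally followed by one lowercase letter, each followed by
#' an optional count). Unknown element symbols are rejected against the
#' element mass table.
#'
#' @param formula Formula string, or an already-parsed named integer vector.
#' @param elements Element mass table (see [element_masses()]).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C19H20ClNO4") # bezafibrate
#' @export
parse_formula <- function(formula, elements = element_masses()) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
      abort_input("`formula` must be a single formula string.")
    }
    stripped <- gsub("\\s", "", formula)
    if (!nzchar(stripped)) {
      abort_input("empty molecular formula")
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", stripped)[[1]]
    tokens <- regmatches(stripped, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(stripped)) {
      abort_input(sprintf("cannot parse formula '%s'", formula))
    }
    sym <- sub("[0-9]*$", "", tokens)
    n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
    n[is.na(n)] <- 1L
    counts <- tapply(n, sym, sum)
  }
  counts <- counts[counts != 0]
  if (length(counts) == 0L) {
    abort_input("empty molecular formula")
  }
  if (any(counts < 0)) {
    abort_input("element counts must be non-negative")
  }
  unknown <- setdiff(names(counts), elements$element)
  if (length(unknown)) {
    abort_input(sprintf("unknown element symbol(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  stats::setNames(as.integer(counts), names(counts))
}

#' Molecular mass of a formula
#'
#' @param formula Formula string or named count vector (see
#'   [parse_formula()]).
#' @param kind `"monoisotopic"` (default) or `"average"`. Intact proteins at
#'   low resolving power are average-mass centroids; small-molecule ligands
#'   are matched monoisotopically.
#' @param elements Element mass table.
#' @return Mass in Da.
#' @examples
#' molecular_mass("H2O")
#' molecular_mass("C19H20ClNO4") # ~361.108, the bezafibrate neutral loss
#' @export
molecular_mass <- function(formula, kind = c("monoisotopic", "average"),
                           elements = element_masses()) {
  kind <- match.arg(kind)
  counts <- parse_formula(formula, elements)
  mass <- elements[[kind]][match(names(counts), elements$element)]
  sum(mass * counts)
}

#' Convert neutral mass to m/z
#'
#' The electrospray relation m/z = (M + z * m_adduct) / z for a z-fold
#' adducted cation.
#'
#' @param mass Neutral mass M in Da (> 0). Vectorised.
#' @param z Positive integer charge. Vectorised.
#' @param adduct Charge carrier, see [adduct_mass()].
#' @return m/z in Da/e.
#' @examples
#' mz_from_mass(14675.4, 8) # ~1835.4, the complex precursor
#' @export
mz_from_mass <- function(mass, z, adduct = "proton") {
  check_number(mass, "mass", positive = TRUE)
  check_number(z, "z", integerish = TRUE, min = 1)
  (mass + z * adduct_mass(adduct)) / z
}

#' Convert m/z to neutral mass
#'
#' Exact inverse of [mz_from_mass()]: M = z * (m/z - m_adduct).
#'
#' @inheritParams mz_from_mass
#' @param mz Observed m/z; must exceed the adduct mass.
#' @return Neutral mass in Da.
#' @examples
#' mass_from_mz(2097.5, 7) # ~14675.4
#' @export
mass_from_mz <- function(mz, z, adduct = "proton") {
  check_number(mz, "mz", positive = TRUE)
  check_number(z, "z", integerish = TRUE, min = 1)
  ma <- adduct_mass(adduct)
  if (any(mz < ma)) {
    abort_input("`mz` must be at least the adduct cation mass.")
  }
  z * mz - z * ma
}

#' Infer the charges of two adjacent charge states
#'
#' Given the m/z of two peaks assumed to be consecutive charge states
#' (z and z - 1) of one protonated species, solve for z:
#' z = round(1 + (mz_low - p) / (mz_high - mz_low)). This is the
#' low-resolution intact-mass trick behind charge-reduced ladders: the
#' spacing of the ladder alone fixes the charges, no isotope resolution
#' needed.
#'
#' @param mz_low,mz_high The two peak positions, `mz_low < mz_high`.
#' @param min_spacing Minimum allowed spacing (m/z); smaller spacings are
#'   rejected as unresolvable.
#' @param max_rounding How far the real-valued charge estimate may sit from
#'   the nearest integer before the call refuses to guess (default 0.3).
#' @param adduct Charge carrier.
#' @return Named integer vector `c(z_low_mz = z, z_high_mz = z - 1)`: the
#'   lower-m/z peak carries the higher charge.
#' @examples
#' infer_charge_pair(2097.5, 2446.9) # the complex pair -> 7, 6
#' infer_charge_pair(2259.9, 2636.3) # heme-bound alpha-globin -> 7, 6
#' @export
infer_charge_pair <- function(mz_low, mz_high, min_spacing = 1,
                              max_rounding = 0.3, adduct = "proton") {
  check_number(mz_low, "mz_low", positive = TRUE)
  check_number(mz_high, "mz_high", positive = TRUE)
  if (mz_high <= mz_low) {
    abort_input("`mz_low` must be strictly below `mz_high`.")
  }
  spacing <- mz_high - mz_low
  if (spacing < min_spacing) {
    rlang::abort(
      sprintf("peak spacing %.3f m/z below minimum %.3f: charge ambiguous",
              spacing, min_spacing),
      class = c("tptcr_ambiguous_charge", "tptcr_error"))
  }
  z_real <- 1 + (mz_low - adduct_mass(adduct)) / spacing
  z <- round(z_real)
  if (abs(z_real - z) > max_rounding) {
    rlang::abort(
      sprintf(paste0("charge estimate %.2f is %.2f from the nearest ",
                     "integer (> %.2f): refusing to guess"),
              z_real, abs(z_real - z), max_rounding),
      class = c("tptcr_ambiguous_charge", "tptcr_error"))
  }
  if (z < 2) {
    abort_input("inferred charges (z, z - 1) must both be >= 1")
  }
  c(z_low_mz = as.integer(z), z_high_mz = as.integer(z) - 1L)
}

#' Predict the charge-reduced product ladder of a precursor
#'
#' Proton transfer charge reduction moves a precursor of charge z to
#' products at z - 1, z - 2, ... Each product's m/z follows from the
#' (conserved) neutral mass. This is the predicted ladder used both to
#' build target tables and as the ground truth the deconvolution module is
#' checked against.
#'
#' @param precursor_mz Precursor m/z.
#' @param z Precursor charge (integer >= 2).
#' @param n_steps Number of charge-reduction steps, `1 <= n_steps < z`.
#' @param adduct Charge carrier.
#' @return A charge ladder: tibble with columns `mz` (strictly increasing)
#'   and `z` (strictly decreasing), with attribute `provenance =
#'   "predicted"`.
#' @examples
#' predict_reduced_ladder(1835.43, 8, 2) # -> 2097.5 (7+), 2446.9 (6+)
#' @export
predict_reduced_ladder <- function(precursor_mz, z, n_steps,
                                   adduct = "proton") {
  check_number(n_steps, "n_steps", integerish = TRUE, min = 1)
  check_number(z, "z", integerish = TRUE, min = 2)
  if (n_steps >= z) {
    abort_input("`n_steps` must be < `z`: cannot reduce below charge 1.")
  }
  mass <- mass_from_mz(precursor_mz, z, adduct)
  zs <- z - seq_len(n_steps)
  ladder <- tibble::tibble(mz = mz_from_mass(mass, zs, adduct),
                           z = as.integer(zs))
  new_charge_ladder(ladder, provenance = "predicted")
}

#' Construct a charge ladder
#'
#' A charge ladder is an ordered set of (m/z, z) pairs attributed to one
#' neutral species: strictly increasing m/z, strictly decreasing distinct
#' charges. It is the substrate of [deconvolve_mass()].
#'
#' @param x A data frame with numeric columns `mz` and `z`.
#' @param provenance `"observed"` or `"predicted"`.
#' @return The ladder as a tibble with class `charge_ladder`.
#' @export
new_charge_ladder <- function(x, provenance = c("observed", "predicted")) {
  provenance <- match.arg(provenance)
  if (!all(c("mz", "z") %in% names(x)) || nrow(x) < 1L) {
    abort_input("a charge ladder needs >= 1 row with columns `mz` and `z`.")
  }
  x <- tibble::as_tibble(x[c("mz", "z")])
  x$z <- as.integer(x$z)
  x <- x[order(x$mz), ]
  if (nrow(x) > 1L && any(diff(x$z) > -1L)) {
    abort_input("ladder charges must be distinct and strictly decreasing in m/z.")
  }
  if (any(x$z < 1L)) abort_input("ladder charges must be >= 1")
  structure(x, provenance = provenance,
            class = c("charge_ladder", class(tibble::tibble())))
}
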