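# Neutral-loss analysis of complex dissociation, small-molecule adduct
# prediction, and a minimal top-down b/y fragment matcher.

#' Mass difference of a same-charge dissociation
#'
#' When a protein-ligand complex dissociates with the ligand departing
#' as a neutral, the protein product retains the precursor charge and
#' the neutral loss is simply delta M = z * (precursor m/z - product
#' m/z). Identical delta M from every retained charge state of the same
#' dissociation is a consistency check.
#'
#' @param precursor_mz,product_mz Precursor and product m/z at the same
#'   charge; `product_mz < precursor_mz`.
#' @param z Retained charge (integer >= 1).
#' @return Neutral loss in Da.
#' @examples
#' neutral_loss(1835.43, 1790.29, 8) # ~361.1, the bezafibrate loss
#' @export
neutral_loss <- function(precursor_mz, product_mz, z) {
  check_number(precursor_mz, "precursor_mz", positive = TRUE)
  check_number(product_mz, "product_mz", positive = TRUE)
  check_number(z, "z", integerish = TRUE, min = 1)
  if (any(product_mz >= precursor_mz)) {
    abort_input("`product_mz` must be strictly below `precursor_mz`.")
  }
  z * (precursor_mz - product_mz)
}

#' Shipped ligand candidate table
#'
#' Small molecules plausibly lost from a liver protein-ligand complex:
#' the dosed drug, the endogenous fatty acids FABP1 carries, heme and
#' water. Monoisotopic masses are computed from the formulas at load
#' time, never stored.
#'
#' @param path Optional CSV with columns `name`, `formula`.
#' @return Tibble `name`, `formula`, `mass` (monoisotopic Da).
#' @export
ligand_candidates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ligand_candidates.csv",
                                package = "tptcr", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tab$mass <- vapply(tab$formula, molecular_mass, numeric(1))
  tab
}

#' Assign a neutral loss to a ligand candidate
#'
#' Candidate minimising |delta M - mass| within tolerance; ties broken
#' toward smaller |difference| then alphabetical name. No match returns
#' an NA row, not an error.
#'
#' @param delta_mass Observed neutral loss (Da).
#' @param candidates Candidate tibble (`name`, `mass`); default the
#'   shipped table.
#' @param tol Tolerance in Da (default 0.5, the low-resolution
#'   intact-mass regime).
#' @return One-row tibble `name`, `mass`, `delta`, `tie`.
#' @examples
#' assign_ligand(361.1)
#' @export
assign_ligand <- function(delta_mass, candidates = ligand_candidates(),
                          tol = 0.5) {
  check_number(delta_mass, "delta_mass", positive = TRUE)
  check_number(tol, "tol", positive = TRUE)
  hit <- match_species(delta_mass, candidates, mass_tol = tol)
  tibble::tibble(name = hit$species, mass = hit$species_mass,
                 delta = hit$delta, tie = hit$tie)
}

#' Predicted singly charged adduct ions of a small molecule
#'
#' The protonated, sodiated and potassiated ions [M+H]+, [M+Na]+,
#' [M+K]+ — the triple by which a free drug is recognised in the
#' low-m/z region of a tissue spectrum.
#'
#' @param formula Molecular formula.
#' @return Tibble `adduct`, `mz` (three rows).
#' @examples
#' small_molecule_ions("C19H20ClNO4")
#' @export
small_molecule_ions <- function(formula) {
  m <- molecular_mass(formula, "monoisotopic")
  adds <- c("proton", "sodium", "potassium")
  tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+K]+"),
    mz = m + unname(vapply(adds, adduct_mass, numeric(1))))
}

# Monoisotopic residue masses of the 20 standard amino acids.
residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.h2o <- 18.0105646

#' Theoretical b/y fragment ions of a peptide or protein sequence
#'
#' Singly charged: b_i = sum of the first i residue masses + proton;
#' y_i = sum of the last i residue masses + H2O + proton. Higher charge
#' states follow as (m + (c - 1) * proton) / c. The full-length b ion
#' (no cleavage) is excluded, so each charge contributes 2 * (L - 1)
#' fragments.
#'
#' @param sequence Residue string (standard 20 one-letter codes,
#'   length >= 2).
#' @param types Fragment types, subset of `c("b", "y")`.
#' @param max_charge Highest fragment charge (default 1; 2 is typical
#'   for top-down data).
#' @return Tibble `type`, `index`, `z`, `mz` with attribute
#'   `sequence_length`.
#' @examples
#' fragment_ions("GG")
#' @export
fragment_ions <- function(sequence, types = c("b", "y"), max_charge = 1) {
  types <- match.arg(types, several.ok = TRUE)
  check_number(max_charge, "max_charge", integerish = TRUE, min = 1)
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) < 2L) {
    abort_input("`sequence` must be a single residue string of length >= 2.")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(unique(res), names(residue_masses))
  if (length(unknown)) {
    abort_input(sprintf("unknown residue(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  m <- unname(residue_masses[res])
  L <- length(m)
  idx <- seq_len(L - 1L)
  singly <- list(
    b = cumsum(m)[idx] + .proton,               # first i residues
    y = cumsum(rev(m))[idx] + .h2o + .proton)   # last i residues
  out <- purrr::map_dfr(types, function(tp) {
    purrr::map_dfr(seq_len(max_charge), function(c) {
      tibble::tibble(type = tp, index = idx, z = as.integer(c),
                     mz = (singly[[tp]] + (c - 1) * .proton) / c)
    })
  })
  attr(out, "sequence_length") <- L
  out
}

#' Match observed peaks against theoretical fragments
#'
#' Greedy nearest-m/z matching within a ppm tolerance; each observed
#' peak and each theoretical fragment is used at most once (pairs are
#' taken in order of increasing |delta ppm|). Sequence coverage is the
#' fraction of the L - 1 backbone cleavage sites hit by at least one
#' matched fragment (site i for b_i, site L - i for y_i).
#'
#' @param theoretical Output of [fragment_ions()].
#' @param observed Observed peaks: numeric m/z vector or tibble with an
#'   `mz` column.
#' @param tol_ppm Match tolerance in ppm (default 10; high-resolution
#'   MS/MS).
#' @return A `fragment_match` object; `tidy()` gives the match table,
#'   `glance()` the coverage summary.
#' @export
match_fragments <- function(theoretical, observed, tol_ppm = 10) {
  check_number(tol_ppm, "tol_ppm", positive = TRUE)
  L <- attr(theoretical, "sequence_length")
  if (is.null(L)) {
    abort_input("`theoretical` must come from fragment_ions().")
  }
  obs <- if (is.numeric(observed)) observed else observed$mz
  matches <- tibble::tibble(type = character(), index = integer(),
                            z = integer(), mz_theoretical = numeric(),
                            mz_observed = numeric(), delta_ppm = numeric(),
                            site = integer())
  if (length(obs) > 0L && nrow(theoretical) > 0L) {
    pairs <- tidyr::expand_grid(ti = seq_len(nrow(theoretical)),
                                oi = seq_along(obs))
    pairs$delta_ppm <- (obs[pairs$oi] - theoretical$mz[pairs$ti]) /
      theoretical$mz[pairs$ti] * 1e6
    pairs <- pairs[abs(pairs$delta_ppm) <= tol_ppm, ]
    pairs <- pairs[order(abs(pairs$delta_ppm)), ]
    used_t <- logical(nrow(theoretical))
    used_o <- logical(length(obs))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$ti[k]
      oi <- pairs$oi[k]
      if (!used_t[ti] && !used_o[oi]) {
        used_t[ti] <- TRUE
        used_o[oi] <- TRUE
        keep[k] <- TRUE
      }
    }
    pairs <- pairs[keep, ]
    if (nrow(pairs) > 0L) {
      th <- theoretical[pairs$ti, ]
      matches <- tibble::tibble(
        type = th$type, index = th$index, z = th$z,
        mz_theoretical = th$mz, mz_observed = obs[pairs$oi],
        delta_ppm = pairs$delta_ppm,
        site = ifelse(th$type == "b", th$index, L - th$index))
    }
  }
  coverage <- length(unique(matches$site)) / (L - 1L)
  structure(list(matches = matches, coverage = coverage,
                 sequence_length = L,
                 n_theoretical = nrow(theoretical), tol_ppm = tol_ppm),
            class = "fragment_match")
}

#' @export
print.fragment_match <- function(x, ...) {
  cat(sprintf(
    "<fragment_match> %d/%d fragments matched, coverage %.1f%% (L = %d)\n",
    nrow(x$matches), x$n_theoretical, 100 * x$coverage,
    x$sequence_length))
  invisible(x)
}
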