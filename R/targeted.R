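# Targeted PTCR: multiplexed target tables, window extraction, and
# product-ion-only image generation. Images are built exclusively from
# charge-reduced product windows so that background ions overlapping a
# precursor m/z cannot contribute.

#' Build a multiplexed targeted-PTCR target table
#'
#' For each species the precursor m/z at its isolation charge state and
#' the first `n_reduced` charge-reduced product m/z values are computed
#' from the neutral mass. Precursors above the quadrupole isolation limit
#' are rejected with an error naming the offenders — multiplexed
#' isolation is only possible through the quadrupole, whose upper m/z
#' limit (2000 on the instrument modelled here) caps which species can
#' be targeted.
#'
#' @param species Tibble with columns `name`, `mass` and `precursor_z`
#'   (or `z0`, rounded).
#' @param n_reduced Number of charge-reduced products per species (>= 1).
#' @param isolation_limit Quadrupole upper m/z isolation limit.
#' @param adduct Charge carrier.
#' @return `TargetTable`: tibble with columns `species`, `precursor_mz`,
#'   `precursor_z` and list-columns `product_z`, `product_mz`.
#' @examples
#' build_target_table(liver_mixture(), n_reduced = 2)
#' @export
build_target_table <- function(species, n_reduced = 2,
                               isolation_limit = 2000, adduct = "proton") {
  check_number(n_reduced, "n_reduced", integerish = TRUE, min = 1)
  if (!"precursor_z" %in% names(species)) {
    if (!"z0" %in% names(species)) {
      abort_input("`species` needs a `precursor_z` (or `z0`) column.")
    }
    species$precursor_z <- as.integer(round(species$z0))
  }
  tab <- tibble::tibble(
    name = species$name,
    mass = species$mass,
    precursor_z = as.integer(species$precursor_z))
  tab <- dplyr::rename(tab, species = "name")
  tab$precursor_mz <- mz_from_mass(tab$mass, tab$precursor_z, adduct)
  over <- tab$precursor_mz >= isolation_limit
  if (any(over)) {
    rlang::abort(
      sprintf("precursor m/z at or above the %g isolation limit: %s",
              isolation_limit,
              paste(sprintf("%s (m/z %.1f)", tab$species[over],
                            tab$precursor_mz[over]), collapse = ", ")),
      class = c("tptcr_isolation_limit", "tptcr_error"))
  }
  ladders <- purrr::map2(tab$precursor_mz, tab$precursor_z,
                         ~predict_reduced_ladder(.x, .y, n_reduced, adduct))
  tab$product_z <- purrr::map(ladders, "z")
  tab$product_mz <- purrr::map(ladders, "mz")
  tab[c("species", "precursor_mz", "precursor_z", "product_z", "product_mz")]
}

#' Integrate a spectrum over an extraction window
#'
#' Total signal within `center +/- half_width`. For profile spectra the
#' Riemann integral (intensity times sampling step) is returned so the
#' value matches the generating centroid intensity of a fully contained
#' peak; for centroid spectra the plain intensity sum. Overlapping
#' windows of different targets are each reported independently (double
#' counting is allowed and logged by callers that care). A window wholly
#' outside the scan returns 0 with a logged warning.
#'
#' @param spectrum An `ms_spectrum`.
#' @param center Window centre, m/z.
#' @param half_width Half-width, m/z (> 0).
#' @return Scalar intensity.
#' @export
extract_window <- function(spectrum, center, half_width = 0.5) {
  check_number(half_width, "half_width", positive = TRUE)
  if (nrow(spectrum) == 0L) {
    return(0)
  }
  lo <- center - half_width
  hi <- center + half_width
  if (hi < min(spectrum$mz) || lo > max(spectrum$mz)) {
    tptcr_log("WARN", sprintf(
      "extraction window [%.2f, %.2f] outside scan range [%.2f, %.2f]",
      lo, hi, min(spectrum$mz), max(spectrum$mz)))
    return(0)
  }
  inside <- spectrum$mz >= lo & spectrum$mz <= hi
  s <- sum(spectrum$intensity[inside])
  if (spectrum_mode(spectrum) == "profile" && nrow(spectrum) > 1L) {
    s <- s * (spectrum$mz[2] - spectrum$mz[1])
  }
  s
}

#' Generate a product-ion-only image for one target
#'
#' Per-pixel intensity is the integral over the target's charge-reduced
#' PRODUCT windows only; the precursor window is deliberately excluded,
#' so any background ion overlapping the precursor m/z cannot leak into
#' the image. Optional per-pixel TIC normalisation divides by the
#' pixel's total integrated signal.
#'
#' @param phantom A `tissue_phantom` (or compatible imaging dataset with
#'   `pixels`, `mz`, `spectra`).
#' @param target One row of a [build_target_table()] table (or the
#'   species name plus the full `targets` table).
#' @param targets Target table, required when `target` is given as a
#'   species name.
#' @param half_width Extraction half-width per product window (m/z).
#' @param normalize `"none"` (default) or `"tic"`.
#' @return `IonImage`: tibble (`row`, `col`, `intensity`) with
#'   attributes `species`, `normalization`, `n_rows`, `n_cols`.
#' @export
product_ion_image <- function(phantom, target, targets = NULL,
                              half_width = 0.5,
                              normalize = c("none", "tic")) {
  normalize <- match.arg(normalize)
  check_number(half_width, "half_width", positive = TRUE)
  if (is.character(target)) {
    if (is.null(targets)) {
      abort_input("`targets` table required when `target` is a name.")
    }
    row <- targets[targets$species == target, ]
    if (nrow(row) != 1L) {
      abort_input(sprintf("target '%s' not found in target table", target))
    }
    target <- row
  }
  if (nrow(target) != 1L) abort_input("`target` must be a single row.")
  if (length(phantom$mz) != ncol(phantom$spectra) ||
      nrow(phantom$pixels) != nrow(phantom$spectra)) {
    abort_input("phantom grid metadata does not match its spectra.")
  }
  step <- phantom$mz[2] - phantom$mz[1]
  product_mz <- target$product_mz[[1]]
  cols <- logical(length(phantom$mz))
  for (pm in product_mz) {
    cols <- cols | (phantom$mz >= pm - half_width &
                      phantom$mz <= pm + half_width)
  }
  if (!any(cols)) {
    tptcr_log("WARN", "no profile samples inside any product window")
  }
  if (normalize == "tic") {
    # TIC normalisation on non-negative signal; pixels with essentially
    # no ion current (below 1% of the median pixel TIC) are set to 0
    # rather than divided by a meaningless denominator
    pos <- pmax(phantom$spectra, 0)
    val <- rowSums(pos[, cols, drop = FALSE]) * step
    tic <- rowSums(pos) * step
    floor_tic <- 0.01 * stats::median(tic)
    val <- ifelse(tic > floor_tic, val / tic, 0)
  } else {
    val <- rowSums(phantom$spectra[, cols, drop = FALSE]) * step
  }
  val <- pmax(val, 0)
  structure(
    tibble::tibble(row = phantom$pixels$row, col = phantom$pixels$col,
                   intensity = val),
    species = target$species, normalization = normalize,
    n_rows = phantom$config$n_rows %||% (max(phantom$pixels$row) + 1L),
    n_cols = phantom$config$n_cols %||% (max(phantom$pixels$col) + 1L),
    class = c("ion_image", class(tibble::tibble())))
}

#' Convert an ion image to a dense matrix
#'
#' @param image An `ion_image` (tibble row, col, intensity; 0-based
#'   coordinates).
#' @return Numeric matrix (rows x cols); pixels absent from the image
#'   (missing scans) are 0.
#' @export
image_matrix <- function(image) {
  nr <- attr(image, "n_rows") %||% (max(image$row) + 1L)
  nc <- attr(image, "n_cols") %||% (max(image$col) + 1L)
  m <- matrix(0, nr, nc)
  m[cbind(image$row + 1L, image$col + 1L)] <- image$intensity
  m
}

#' Two-channel composite of a pair of ion images
#'
#' Each channel is min-max scaled to [0, 1] independently (so the
#' qualitative contrast is preserved irrespective of absolute units),
#' then combined into red and blue channels of one RGB image — the
#' standard rendering for a vessel marker (red) against a bulk-tissue
#' species (blue).
#'
#' @param image_red,image_blue `ion_image`s with identical dimensions.
#' @return Tibble (`row`, `col`, `red`, `blue`) with class
#'   `composite_image`; write with [write_composite_png()].
#' @export
composite_image <- function(image_red, image_blue) {
  if (!identical(dim(image_matrix(image_red)),
                 dim(image_matrix(image_blue)))) {
    abort_input("composite channels must share dimensions.")
  }
  scale01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) {
      return(rep(0, length(v)))
    }
    (v - r[1]) / diff(r)
  }
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(image_red), red = "intensity"),
    dplyr::rename(tibble::as_tibble(image_blue), blue = "intensity"),
    by = c("row", "col"))
  joined$red <- scale01(joined$red)
  joined$blue <- scale01(joined$blue)
  structure(joined,
            n_rows = attr(image_red, "n_rows"),
            n_cols = attr(image_red, "n_cols"),
            species = c(red = attr(image_red, "species"),
                        blue = attr(image_blue, "species")),
            class = c("composite_image", class(tibble::tibble())))
}

#' Contrast ratio between two regions of an ion image
#'
#' Ratio of mean intensity in region `a` to region `b` — e.g. the
#' vessel/bulk contrast that separates a vasculature marker from a
#' bulk-tissue species. If region `b` has zero mean while `a` does not,
#' `Inf` is returned as a sentinel.
#'
#' @param image An `ion_image`.
#' @param pixels Pixel-region tibble (`row`, `col`, `region`), e.g.
#'   `phantom$pixels`.
#' @param a,b Region names (default `"vessel"` vs `"bulk"`).
#' @return Scalar ratio mean(a) / mean(b).
#' @export
region_contrast <- function(image, pixels, a = "vessel", b = "bulk") {
  joined <- dplyr::inner_join(tibble::as_tibble(image), pixels,
                              by = c("row", "col"))
  ia <- joined$intensity[joined$region == a]
  ib <- joined$intensity[joined$region == b]
  if (length(ia) == 0L || length(ib) == 0L) {
    abort_input(sprintf("regions '%s' and '%s' must both be non-empty.",
                        a, b))
  }
  ma <- mean(ia)
  mb <- mean(ib)
  if (mb == 0) {
    if (ma > 0) {
      return(Inf)
    }
    return(NaN)
  }
  ma / mb
}
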