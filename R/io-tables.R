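# CSV target tables, ion-image output (PNG render + plain-text matrix)
# and run manifests. CSV dialect: comma-separated, UTF-8, mandatory
# header, '.' decimal separator.

#' Write a target table as CSV
#'
#' Column schema: `name`, `precursor_mz`, `precursor_z`,
#' `product_charges` (semicolon-separated), `product_mz`
#' (semicolon-separated). Product values are derived quantities; on
#' reading they are recomputed from the precursor and validated against
#' the file.
#'
#' @param targets A [build_target_table()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(targets, path) {
  out <- tibble::tibble(
    name = targets$species,
    precursor_mz = round(targets$precursor_mz, 4),
    precursor_z = targets$precursor_z,
    product_charges = vapply(targets$product_z, paste,
                             character(1), collapse = ";"),
    product_mz = vapply(targets$product_mz,
                        function(v) paste(round(v, 4), collapse = ";"),
                        character(1)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a target table from CSV
#'
#' @param path CSV path (schema of [write_target_table()]).
#' @param adduct Charge carrier.
#' @return Target table tibble; product m/z recomputed from the
#'   precursor mass, with a parse error if the stored values disagree by
#'   more than 0.01 m/z.
#' @export
read_target_table <- function(path, adduct = "proton") {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "precursor_mz", "precursor_z", "product_charges")
  if (!all(need %in% names(tab))) {
    rlang::abort(sprintf("target table missing column(s): %s",
                         paste(setdiff(need, names(tab)), collapse = ", ")),
                 class = c("tptcr_parse_error", "tptcr_error"))
  }
  parse_ints <- function(s) as.integer(strsplit(s, ";")[[1]])
  out <- tibble::tibble(
    species = tab$name,
    precursor_mz = tab$precursor_mz,
    precursor_z = as.integer(tab$precursor_z),
    product_z = lapply(tab$product_charges, parse_ints))
  out$product_mz <- purrr::pmap(
    list(out$precursor_mz, out$precursor_z, out$product_z),
    function(pmz, pz, zs) {
      mass <- mass_from_mz(pmz, pz, adduct)
      mz_from_mass(mass, zs, adduct)
    })
  if ("product_mz" %in% names(tab)) {
    stored <- lapply(tab$product_mz,
                     function(s) as.numeric(strsplit(s, ";")[[1]]))
    dev <- max(abs(unlist(stored) - unlist(out$product_mz)))
    if (dev > 0.01) {
      rlang::abort(sprintf(
        "stored product m/z disagree with recomputed values by %.4f", dev),
        class = c("tptcr_parse_error", "tptcr_error"))
    }
  }
  out
}

#' Write an ion image as PNG plus a plain-text matrix
#'
#' The PNG is a min-max scaled grayscale render for quick inspection;
#' the tab-separated text matrix alongside (`<path>.txt`) carries the
#' exact intensities.
#'
#' @param image An `ion_image`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_ion_image <- function(image, path) {
  m <- image_matrix(image)
  rng <- range(m)
  scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  png::writePNG(scaled, path)
  utils::write.table(m, sub("\\.png$", ".txt", path), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a two-channel composite image as PNG
#'
#' Red and blue channels from [composite_image()]; green is zero.
#'
#' @param comp A `composite_image`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_composite_png <- function(comp, path) {
  nr <- attr(comp, "n_rows")
  nc <- attr(comp, "n_cols")
  arr <- array(0, c(nr, nc, 3))
  idx <- cbind(comp$row + 1L, comp$col + 1L)
  arr[cbind(idx, 1L)] <- comp$red
  arr[cbind(idx, 3L)] <- comp$blue
  png::writePNG(arr, path)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and MD5 hashes of the input files of
#' a run: together with the package version this is sufficient to
#' reproduce the outputs bit-exactly.
#'
#' @param path Output JSON path.
#' @param config Named list of run parameters (must include the seed
#'   when any randomness was used).
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), inputs = character()) {
  hashes <- if (length(inputs)) {
    stats::setNames(as.list(unname(tools::md5sum(inputs))), inputs)
  } else {
    NULL
  }
  jsonlite::write_json(
    list(package = "tptcr",
         version = as.character(utils::packageVersion("tptcr")),
         config = config, input_md5 = hashes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
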