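# Continuous-mode imzML I/O for phantom imaging datasets.
#
# imzML splits an imaging run into an XML index (.imzML) and a raw binary
# (.ibd) holding the arrays. In continuous mode every pixel shares one m/z
# axis, which is exactly the simulator's representation, so that mode is
# written. No imzML reader exists in this R stack, so a minimal writer /
# reader pair for the continuous-mode subset is implemented here with
# xml2; files written by it follow the published imzML layout (16-byte
# UUID at the head of the .ibd, 64-bit floats, external offset/length
# attributes, MD5 checksum) and are readable by standard imzML parsers.

imzml_ns <- "http://psi.hupo.org/ms/mzml"

#' Write an imaging dataset as continuous-mode imzML
#'
#' Writes `<path>.imzML` plus `<path>.ibd`, alongside plain-text ground
#' truth (`<path>_truth.csv`, `<path>_pixels.csv`) and a JSON manifest
#' (`<path>_manifest.json` with seed and generator parameters) when the
#' dataset is a simulated phantom.
#'
#' @param phantom A `tissue_phantom` (or any list with `pixels`, `mz`,
#'   `spectra`).
#' @param path Output path without extension (or ending in `.imzML`).
#' @return Base path, invisibly.
#' @export
write_imzml <- function(phantom, path) {
  base <- sub("\\.imzML$", "", path)
  ibd_path <- paste0(base, ".ibd")
  xml_path <- paste0(base, ".imzML")

  mz <- phantom$mz
  spectra <- phantom$spectra
  n_px <- nrow(spectra)
  uuid_raw <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)

  con <- file(ibd_path, "wb")
  writeBin(uuid_raw, con)
  writeBin(as.numeric(mz), con, size = 8, endian = "little")
  mz_offset <- 16
  mz_len <- length(mz)
  px_offsets <- numeric(n_px)
  off <- 16 + 8 * mz_len
  for (i in seq_len(n_px)) {
    writeBin(as.numeric(spectra[i, ]), con, size = 8, endian = "little")
    px_offsets[i] <- off
    off <- off + 8 * mz_len
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd_path))

  uuid_hex <- paste(sprintf("%02x", as.integer(uuid_raw)), collapse = "")
  uuid_fmt <- sprintf("{%s-%s-%s-%s-%s}",
                      substr(uuid_hex, 1, 8), substr(uuid_hex, 9, 12),
                      substr(uuid_hex, 13, 16), substr(uuid_hex, 17, 20),
                      substr(uuid_hex, 21, 32))

  nr <- phantom$config$n_rows %||% (max(phantom$pixels$row) + 1L)
  nc <- phantom$config$n_cols %||% (max(phantom$pixels$col) + 1L)

  doc <- xml2::xml_new_root("mzML", xmlns = imzml_ns, version = "1.1")
  fdesc <- xml2::xml_add_child(doc, "fileDescription")
  fcont <- xml2::xml_add_child(fdesc, "fileContent")
  add_cv <- function(node, accession, name, value = NULL) {
    cv <- xml2::xml_add_child(node, "cvParam",
                              cvRef = if (grepl("^IMS", accession)) "IMS" else "MS",
                              accession = accession, name = name)
    if (!is.null(value)) xml2::xml_set_attr(cv, "value", as.character(value))
    cv
  }
  add_cv(fcont, "IMS:1000030", "continuous")
  add_cv(fcont, "IMS:1000080", "universally unique identifier", uuid_fmt)
  add_cv(fcont, "IMS:1000091", "ibd MD5", md5)

  scan_settings <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  ss <- xml2::xml_add_child(scan_settings, "scanSettings", id = "scansettings1")
  add_cv(ss, "IMS:1000042", "max count of pixels x", nc)
  add_cv(ss, "IMS:1000043", "max count of pixels y", nr)

  run <- xml2::xml_add_child(doc, "run", id = "run1")
  specs <- xml2::xml_add_child(run, "spectrumList", count = as.character(n_px))
  for (i in seq_len(n_px)) {
    sp <- xml2::xml_add_child(specs, "spectrum",
                              id = sprintf("spectrum=%d", i),
                              index = as.character(i - 1L),
                              defaultArrayLength = as.character(mz_len))
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    sc <- xml2::xml_add_child(scl, "scan")
    # imzML position indices are 1-based; internal coordinates 0-based
    add_cv(sc, "IMS:1000050", "position x", phantom$pixels$col[i] + 1L)
    add_cv(sc, "IMS:1000051", "position y", phantom$pixels$row[i] + 1L)
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    mzb <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
    add_cv(mzb, "MS:1000514", "m/z array")
    add_cv(mzb, "IMS:1000102", "external offset", mz_offset)
    add_cv(mzb, "IMS:1000103", "external array length", mz_len)
    xml2::xml_add_child(mzb, "binary")
    inb <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
    add_cv(inb, "MS:1000515", "intensity array")
    add_cv(inb, "IMS:1000102", "external offset", px_offsets[i])
    add_cv(inb, "IMS:1000103", "external array length", mz_len)
    xml2::xml_add_child(inb, "binary")
  }
  xml2::write_xml(doc, xml_path)

  if (!is.null(phantom$truth)) {
    readr::write_csv(phantom$truth, paste0(base, "_truth.csv"),
                     progress = FALSE)
    readr::write_csv(phantom$pixels, paste0(base, "_pixels.csv"),
                     progress = FALSE)
    cfg <- phantom$config
    cfg$acquisition <- unclass(cfg$acquisition)
    jsonlite::write_json(
      list(generator = "tptcr::generate_phantom", config = cfg,
           ibd_md5 = md5, uuid = uuid_fmt),
      paste0(base, "_manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(base)
}

#' Read a continuous-mode imzML imaging dataset
#'
#' Reads the subset of imzML written by [write_imzml()] (continuous mode,
#' 64-bit floats). Pixels are returned 0-based row-major; a
#' non-rectangular coordinate set is padded to its bounding box with an
#' all-zero spectrum and flagged in the QC mask; duplicated coordinates
#' are an error naming the pixel.
#'
#' @param path Path to the `.imzML` file (or base path).
#' @return List with `pixels` (row, col, region = NA, qc_missing),
#'   `mz`, `spectra`, `truth` (if the sidecar CSV exists) and `config`
#'   (from the manifest, if present).
#' @export
read_imzml <- function(path) {
  base <- sub("\\.imzML$", "", path)
  xml_path <- paste0(base, ".imzML")
  ibd_path <- paste0(base, ".ibd")
  if (!file.exists(xml_path) || !file.exists(ibd_path)) {
    abort_input(sprintf("missing %s or %s", xml_path, ibd_path))
  }
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    rlang::abort(sprintf("cannot parse '%s': %s", xml_path,
                         conditionMessage(e)),
                 class = c("tptcr_parse_error", "tptcr_error"))
  })
  xml2::xml_ns_strip(doc)
  spectra_nodes <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra_nodes) == 0L) {
    rlang::abort("no spectra in imzML index",
                 class = c("tptcr_parse_error", "tptcr_error"))
  }
  get_cv <- function(node, accession) {
    n <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession))
    xml2::xml_attr(n, "value")
  }
  info <- purrr::map_dfr(spectra_nodes, function(sp) {
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    is_mz <- vapply(arrays, function(a) {
      !is.na(xml2::xml_find_first(a, ".//cvParam[@accession='MS:1000514']") |>
               xml2::xml_attr("accession"))
    }, logical(1))
    tibble::tibble(
      col = as.integer(get_cv(sp, "IMS:1000050")) - 1L,
      row = as.integer(get_cv(sp, "IMS:1000051")) - 1L,
      mz_offset = as.numeric(get_cv(arrays[is_mz][[1]], "IMS:1000102")),
      mz_len = as.integer(get_cv(arrays[is_mz][[1]], "IMS:1000103")),
      int_offset = as.numeric(get_cv(arrays[!is_mz][[1]], "IMS:1000102")),
      int_len = as.integer(get_cv(arrays[!is_mz][[1]], "IMS:1000103")))
  })
  dup <- duplicated(info[c("row", "col")])
  if (any(dup)) {
    abort_input(sprintf("coordinate collision at pixel (row=%d, col=%d)",
                        info$row[which(dup)[1]], info$col[which(dup)[1]]))
  }
  con <- file(ibd_path, "rb")
  on.exit(close(con))
  seek(con, info$mz_offset[1])
  mz <- readBin(con, numeric(), n = info$mz_len[1], size = 8,
                endian = "little")
  nr <- max(info$row) + 1L
  nc <- max(info$col) + 1L
  px <- tidyr::expand_grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  px$qc_missing <- TRUE
  spectra <- matrix(0, nrow(px), length(mz))
  for (i in seq_len(nrow(info))) {
    seek(con, info$int_offset[i])
    v <- readBin(con, numeric(), n = info$int_len[i], size = 8,
                 endian = "little")
    k <- which(px$row == info$row[i] & px$col == info$col[i])
    spectra[k, ] <- v
    px$qc_missing[k] <- FALSE
  }
  if (any(px$qc_missing)) {
    tptcr_log("WARN", sprintf(
      "%d pixel(s) missing from imzML; padded with zeros and flagged",
      sum(px$qc_missing)))
  }
  truth_path <- paste0(base, "_truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  manifest_path <- paste0(base, "_manifest.json")
  config <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)$config
  } else {
    list(n_rows = nr, n_cols = nc)
  }
  config$n_rows <- config$n_rows %||% nr
  config$n_cols <- config$n_cols %||% nc
  list(pixels = px, mz = mz, spectra = spectra, truth = truth,
       config = config)
}
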