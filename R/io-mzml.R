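# mzML single-scan I/O through mzR (proteowizard backend).

#' Write a spectrum to mzML
#'
#' Centroid data round-trip bit-exactly; profile data round-trip to
#' float/double precision of the encoder.
#'
#' @param spectrum An `ms_spectrum`.
#' @param path Output path ending in `.mzML`.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectrum, path) {
  if (nrow(spectrum) == 0L) {
    abort_input("refusing to write an empty spectrum.")
  }
  pk <- list(cbind(mz = spectrum$mz, intensity = spectrum$intensity))
  centroided <- spectrum_mode(spectrum) == "centroid"
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = nrow(spectrum),
    totIonCurrent = sum(spectrum$intensity),
    retentionTime = 0.0,
    basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
    basePeakIntensity = max(spectrum$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "", spectrumId = "scan=1",
    centroided = centroided, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(spectrum$mz),
    scanWindowUpperLimit = max(spectrum$mz))
  mzR::writeMSData(object = pk, file = path, header = hdr)
  invisible(path)
}

#' Read a spectrum from mzML
#'
#' @param path Path to an mzML file.
#' @param scan Scan number (default 1).
#' @return An `ms_spectrum`; mode taken from the file's centroided flag.
#' @export
read_mzml <- function(path, scan = 1) {
  if (!file.exists(path)) {
    abort_input(sprintf("file not found: %s", path))
  }
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) {
                       rlang::abort(
                         sprintf("cannot parse '%s': %s", path,
                                 conditionMessage(e)),
                         class = c("tptcr_parse_error", "tptcr_error"))
                     })
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (scan > nrow(hdr)) {
    abort_input(sprintf("scan %d not present (%d scans)", scan, nrow(hdr)))
  }
  pk <- mzR::peaks(handle, scan)
  centroided <- isTRUE(hdr$centroided[scan])
  new_spectrum(pk[, 1], pk[, 2],
               mode = if (centroided) "centroid" else "profile",
               metadata = list(path = path, scan = scan))
}
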