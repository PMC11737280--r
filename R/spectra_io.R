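#' Construct a raw mass spectrum
#'
#' A raw spectrum is the as-acquired m/z--intensity trace of one MALDI-TOF
#' acquisition (one spot of one specimen). m/z must be strictly increasing
#' and intensities non-negative and finite.
#'
#' @param mz numeric vector of mass-to-charge values (Da), strictly increasing.
#' @param intensity numeric vector of non-negative intensities, same length.
#' @param spectrum_id unique identifier string.
#' @return an object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, spectrum_id) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop_ccimatch("raw_spectrum: mz and intensity lengths differ")
  if (length(mz) < 2L)
    stop_ccimatch("raw_spectrum: need at least 2 points")
  if (any(!is.finite(mz)) || any(diff(mz) <= 0))
    stop_ccimatch("raw_spectrum: mz must be finite and strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_ccimatch("raw_spectrum: intensities must be finite and >= 0")
  structure(list(mz = mz, intensity = intensity,
                 spectrum_id = as.character(spectrum_id)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum %s: %d points, m/z %.1f-%.1f Da>\n",
              x$spectrum_id, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

# ---- mzXML ------------------------------------------------------------------

decode_peaks <- function(b64, precision, n_peaks) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  size <- if (precision == 32L) 4L else 8L
  vals <- readBin(raw, what = "double", n = length(raw) %/% size,
                  size = size, endian = "big")
  if (n_peaks > 0 && length(vals) < 2L * n_peaks)
    stop_ccimatch("mzXML peaks block shorter than peaksCount")
  vals
}

#' Read raw spectra from an mzXML file
#'
#' Reads every scan of an mzXML file into a list of [raw_spectrum] objects.
#' m/z values are sorted ascending if the file stores them unsorted. Scans
#' with zero peaks are skipped with a warning. Only uncompressed, network
#' byte order peak blocks (precision 32 or 64) are supported.
#'
#' @param path path to an mzXML file.
#' @return list of `raw_spectrum`, ids `<file stem>.scan<num>`.
#' @export
read_mzxml <- function(path) {
  if (!file.exists(path)) stop_ccimatch("mzXML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop_ccimatch("malformed mzXML in '", path, "': ",
                                  conditionMessage(e)))
  scans <- xml2::xml_find_all(doc, "//*[local-name()='scan']")
  if (length(scans) == 0L)
    stop_ccimatch("no <scan> elements in mzXML file: ", path)
  stem <- sub("\\.mzxml$", "", basename(path), ignore.case = TRUE)
  out <- list()
  for (i in seq_along(scans)) {
    scan <- scans[[i]]
    num <- xml2::xml_attr(scan, "num")
    if (is.na(num)) num <- as.character(i)
    n_peaks <- suppressWarnings(as.integer(xml2::xml_attr(scan, "peaksCount")))
    peaks <- xml2::xml_find_first(scan, "./*[local-name()='peaks']")
    if (is.na(n_peaks)) n_peaks <- NA_integer_
    if ((!is.na(n_peaks) && n_peaks == 0L) || inherits(peaks, "xml_missing")) {
      warning("skipping scan ", num, " of '", basename(path),
              "': zero peaks", call. = FALSE)
      next
    }
    comp <- xml2::xml_attr(peaks, "compressionType")
    if (!is.na(comp) && !comp %in% c("none", ""))
      stop_ccimatch("compressed mzXML peaks are not supported (scan ", num, ")")
    precision <- suppressWarnings(as.integer(xml2::xml_attr(peaks, "precision")))
    if (is.na(precision)) precision <- 32L
    vals <- decode_peaks(xml2::xml_text(peaks), precision,
                         if (is.na(n_peaks)) 0L else n_peaks)
    mz <- vals[seq(1L, length(vals), by = 2L)]
    it <- vals[seq(2L, length(vals), by = 2L)]
    if (is.unsorted(mz, strictly = TRUE)) {
      o <- order(mz)
      mz <- mz[o]
      it <- it[o]
    }
    out[[length(out) + 1L]] <-
      raw_spectrum(mz, pmax(it, 0), sprintf("%s.scan%s", stem, num))
  }
  out
}

#' Write raw spectra to an mzXML file
#'
#' Minimal mzXML writer (one `<scan>` per spectrum, 64-bit network byte
#' order, uncompressed). Round-trips exactly with [read_mzxml].
#'
#' @param spectra a `raw_spectrum` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(spectra, path) {
  if (inherits(spectra, "raw_spectrum")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="ISO-8859-1"?>',
               '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
               sprintf(' <msRun scanCount="%d">', length(spectra))), con)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    interleaved <- as.vector(rbind(s$mz, s$intensity))
    b64 <- jsonlite::base64_enc(writeBin(interleaved, raw(), size = 8L,
                                         endian = "big"))
    b64 <- gsub("[[:space:]]", "", b64)
    writeLines(c(
      sprintf('  <scan num="%d" msLevel="1" peaksCount="%d">', i, length(s$mz)),
      sprintf('   <peaks precision="64" byteOrder="network" contentType="m/z-int" compressionType="none">%s</peaks>', b64),
      "  </scan>"), con)
  }
  writeLines(c(" </msRun>", "</mzXML>"), con)
  invisible(path)
}

# ---- plain-text spectra -----------------------------------------------------

#' Read a two-column m/z--intensity table as a raw spectrum
#'
#' Accepts whitespace- or tab-delimited text with or without a header; the
#' first two columns are taken as m/z (Da) and intensity.
#'
#' @param path input file.
#' @param spectrum_id identifier; default is the file stem.
#' @return a `raw_spectrum`.
#' @export
read_spectrum_table <- function(path, spectrum_id = NULL) {
  if (!file.exists(path)) stop_ccimatch("spectrum table not found: ", path)
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         colClasses = NA, stringsAsFactors = FALSE)
  if (suppressWarnings(is.na(as.numeric(d[1, 1])))) d <- d[-1, , drop = FALSE]
  mz <- as.numeric(d[[1]])
  it <- as.numeric(d[[2]])
  o <- order(mz)
  raw_spectrum(mz[o], it[o],
               spectrum_id %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Write a raw spectrum as a two-column table
#' @param spectrum a `raw_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectrum, path) {
  data.table::fwrite(data.table::data.table(mz = spectrum$mz,
                                            intensity = spectrum$intensity),
                     path, sep = "\t")
  invisible(path)
}

# ---- metadata ---------------------------------------------------------------

#' Read and validate a spectrum metadata table
#'
#' The table links every spectrum to its specimen, spot (technical
#' replicate) index, species label and panel assignment. Required columns:
#' `spectrum_id`, `specimen_id`, `spot_index`, `species_label`, `panel`.
#' `panel` is case-normalized and must be `reference` or `test`;
#' `(specimen_id, spot_index)` must be unique.
#'
#' @param path tab-separated file with a header row.
#' @return a `data.frame` of validated metadata records.
#' @export
read_metadata <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t",
                                       colClasses = list(character = "spectrum_id")))
  validate_metadata(d)
}

#' Validate an in-memory metadata table
#' @param d data.frame with the metadata schema of [read_metadata].
#' @return the validated, normalized data.frame.
#' @export
validate_metadata <- function(d) {
  required <- c("spectrum_id", "specimen_id", "spot_index",
                "species_label", "panel")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop_ccimatch("metadata is missing column(s): ",
                  paste(missing, collapse = ", "))
  d$spectrum_id <- as.character(d$spectrum_id)
  d$specimen_id <- as.character(d$specimen_id)
  d$species_label <- as.character(d$species_label)
  d$spot_index <- as.integer(d$spot_index)
  d$panel <- tolower(as.character(d$panel))
  if (any(is.na(d$spot_index)) || any(d$spot_index < 1L))
    stop_ccimatch("spot_index must be an integer >= 1")
  bad_panel <- setdiff(unique(d$panel), c("reference", "test"))
  if (length(bad_panel) > 0)
    stop_ccimatch("panel must be 'reference' or 'test'; found: ",
                  paste(bad_panel, collapse = ", "))
  key <- paste(d$specimen_id, d$spot_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_ccimatch("duplicated (specimen_id, spot_index): ",
                  paste(gsub("\r", "/", dup), collapse = ", "))
  }
  if (anyDuplicated(d$spectrum_id))
    stop_ccimatch("duplicated spectrum_id: ",
                  paste(unique(d$spectrum_id[duplicated(d$spectrum_id)]),
                        collapse = ", "))
  d[required]
}

# ---- result tables ----------------------------------------------------------

#' Write a results table as TSV
#'
#' Tab-separated with header. `-Inf` values (log10(CCI) of fully dissimilar
#' pairs) serialize as the literal string `-Inf`, which common numeric
#' parsers (R, pandas) read back as negative infinity.
#'
#' @param records a data.frame of result records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table]
#' @param path input path.
#' @return data.frame; `-Inf` cells are parsed back to negative infinity.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
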