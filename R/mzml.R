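# Minimal mzML ingestion/export for ion-mobility MS1 peak data.
#
# The reader handles the two ways 1/K0 shows up in mzML from timsTOF-style
# instruments: a spectrum-level cvParam ("inverse reduced ion mobility",
# MS:1002815) or a per-peak binary data array ("mean inverse reduced ion
# mobility array", MS:1002816). The writer emits one MS1 spectrum per scan
# cycle with m/z, intensity, and ion-mobility arrays (64-bit, uncompressed).

#' Read MS1 peaks with ion mobility from an mzML file
#'
#' MS1 spectra contribute one peak per (m/z, intensity) array entry, at the
#' spectrum's scan start time, with ion mobility taken from a per-peak
#' mobility array when present, else from the spectrum-level mobility
#' value. MS2 spectra are ignored.
#'
#' @param path Path to an mzML file.
#' @param run_id Run label; defaults to file name without extension.
#' @return A peak tibble as from [read_peak_tsv()].
#' @export
read_mzml_im <- function(path, run_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed mzML XML in ", path, ": ", conditionMessage(e)),
          class = "lfq4d_format_error")
  })
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  parsed <- lapply(spectra, parse_mzml_spectrum)
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]  # drop non-MS1
  if (!length(parsed)) {
    warn(paste0(path, ": no MS1 spectra found; returning an empty run"))
    return(new_run_peaks(
      tibble(rt = double(), mz = double(), im = double(),
             intensity = double()),
      run_id))
  }
  has_im <- vapply(parsed, function(s) !is.null(s$im), logical(1))
  if (!any(has_im)) {
    abort(paste0(path, ": no ion-mobility annotation found on any MS1 ",
                 "spectrum (need a spectrum-level inverse reduced ion ",
                 "mobility value or a mobility array)"),
          class = "lfq4d_unsupported_input")
  }
  if (!all(has_im)) {
    abort(paste0(path, ": some MS1 spectra lack ion-mobility annotation"),
          class = "lfq4d_unsupported_input")
  }
  x <- tibble(
    rt = unlist(lapply(parsed, function(s) rep(s$rt, length(s$mz)))),
    mz = unlist(lapply(parsed, `[[`, "mz")),
    im = unlist(lapply(parsed, `[[`, "im")),
    intensity = unlist(lapply(parsed, `[[`, "intensity"))
  )
  validate_peaks(x, source = path)
  new_run_peaks(x, run_id)
}

# returns list(rt, mz, intensity, im) for an MS1 spectrum, NULL otherwise
parse_mzml_spectrum <- function(sp) {
  cv <- xml2::xml_find_all(sp, "./cvParam")
  acc <- xml2::xml_attr(cv, "accession")
  val <- xml2::xml_attr(cv, "value")
  ms_level <- val[acc == "MS:1000511"]
  if (!length(ms_level) || ms_level[1] != "1") return(NULL)

  scan_cv <- xml2::xml_find_all(sp, ".//scan/cvParam")
  sacc <- xml2::xml_attr(scan_cv, "accession")
  sval <- xml2::xml_attr(scan_cv, "value")
  sunit <- xml2::xml_attr(scan_cv, "unitName")
  rt_i <- which(sacc == "MS:1000016")[1]
  if (is.na(rt_i)) abort("mzML spectrum without scan start time",
                         class = "lfq4d_format_error")
  rt <- as.numeric(sval[rt_i])
  if (!is.na(sunit[rt_i]) && sunit[rt_i] == "second") rt <- rt / 60

  im_scalar <- c(sval[sacc == "MS:1002815"], val[acc == "MS:1002815"])
  arrays <- lapply(xml2::xml_find_all(sp, ".//binaryDataArray"),
                   parse_binary_array)
  kinds <- vapply(arrays, `[[`, character(1), "kind")
  pick <- function(kind) {
    i <- which(kinds == kind)[1]
    if (is.na(i)) NULL else arrays[[i]]$values
  }
  mz <- pick("mz")
  intensity <- pick("intensity")
  if (is.null(mz) || is.null(intensity)) {
    abort("mzML MS1 spectrum lacks m/z or intensity array",
          class = "lfq4d_format_error")
  }
  im <- pick("im")
  if (is.null(im) && length(im_scalar)) {
    im <- rep(as.numeric(im_scalar[1]), length(mz))
  }
  list(rt = rt, mz = mz, intensity = intensity, im = im)
}

parse_binary_array <- function(node) {
  cv <- xml2::xml_find_all(node, "./cvParam")
  acc <- xml2::xml_attr(cv, "accession")
  nm <- xml2::xml_attr(cv, "name")
  kind <- if ("MS:1000514" %in% acc) "mz"
          else if ("MS:1000515" %in% acc) "intensity"
          else if ("MS:1002816" %in% acc ||
                   any(grepl("inverse reduced ion mobility", nm))) "im"
          else "other"
  size <- if ("MS:1000521" %in% acc) 4L else 8L  # 32- vs 64-bit float
  b64 <- xml2::xml_text(xml2::xml_find_first(node, "./binary"))
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if ("MS:1000574" %in% acc) raw <- memDecompress(raw, type = "gzip")
  values <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                    endian = "little")
  list(kind = kind, values = values)
}

#' Write MS1 peaks with ion mobility to an mzML file
#'
#' Emits one MS1 spectrum per scan cycle (distinct retention time), each
#' carrying uncompressed 64-bit m/z, intensity, and inverse-reduced-ion-
#' mobility binary arrays. The output is a minimal but standard-conforming
#' mzML document readable by [read_mzml_im()] and by general mzML readers
#' (which will see the m/z and intensity arrays).
#'
#' @param peaks Peak tibble (`rt`, `mz`, `im`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml_im <- function(peaks, path) {
  validate_peaks(peaks)
  rid <- run_id(peaks)
  if (is.na(rid)) rid <- "run"
  grid <- rt_grid(peaks)
  idx <- split(seq_len(nrow(peaks)), match(peaks$rt, grid))
  b64 <- function(x) {
    gsub("[\r\n]", "", jsonlite::base64_enc(
      writeBin(as.double(x), raw(), size = 8L, endian = "little")))
  }
  array_xml <- function(x, acc, name, unit = "") {
    enc <- b64(x)
    paste0(
      '<binaryDataArray encodedLength="', nchar(enc), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="', acc, '" name="', name, '"', unit,
      '/>', '<binary>', enc, '</binary></binaryDataArray>')
  }
  spectra <- vapply(seq_along(grid), function(i) {
    rows <- idx[[as.character(i)]]
    if (is.null(rows)) rows <- integer()
    paste0(
      '<spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', length(rows), '">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" ',
      'value="', format_num(grid[i]),
      '" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="3">',
      array_xml(peaks$mz[rows], "MS:1000514", "m/z array",
                ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
      array_xml(peaks$intensity[rows], "MS:1000515", "intensity array"),
      array_xml(peaks$im[rows], "MS:1002816",
                "mean inverse reduced ion mobility array"),
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass ',
    'Spectrometry Ontology" URI="https://raw.githubusercontent.com/',
    'HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.',
    'githubusercontent.com/bio-ontology-research-group/unit-ontology/',
    'master/unit.obo"/>',
    '</cvList>',
    '<run id="', rid, '">',
    '<spectrumList count="', length(grid), '">',
    paste0(spectra, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}
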