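#' Read a centroided MS1 peak table
#'
#' Reads a tab-separated peak table with columns `rt_min`, `mz`, `im_1k0`,
#' `intensity` into a peak tibble. Each row is one centroided MS1 point:
#' retention time in minutes, m/z in Thomson, inverse reduced ion mobility
#' (1/K0, Vs/cm2), and abundance.
#'
#' @param path Path to the TSV file.
#' @param run_id Run label attached to the result; defaults to the file
#'   name without extension.
#' @return A tibble with columns `rt`, `mz`, `im`, `intensity` and
#'   attribute `run_id`. Row order is preserved as read. Use [rt_grid()]
#'   for the sorted distinct scan-cycle retention times.
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("rt_min\tmz\tim_1k0\tintensity",
#'              "10.0\t500.1\t0.90\t1200"), p)
#' read_peak_tsv(p, run_id = "demo")
read_peak_tsv <- function(path, run_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  required <- c("rt_min", "mz", "im_1k0", "intensity")
  missing_col <- setdiff(required, hdr)
  if (length(missing_col)) {
    abort(paste0("peak table ", path, " is missing required column(s): ",
                 paste(missing_col, collapse = ", ")),
          class = "lfq4d_format_error")
  }
  # numeric fields come in as text and go through strtod (correctly
  # rounded), so write -> read round-trips doubles exactly
  x <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, locale = readr::locale(decimal_mark = "."))
  x <- tibble(rt = as.numeric(x$rt_min), mz = as.numeric(x$mz),
              im = as.numeric(x$im_1k0),
              intensity = as.numeric(x$intensity))
  validate_peaks(x, source = path)
  new_run_peaks(x, run_id)
}

#' Write a peak table to TSV
#'
#' Inverse of [read_peak_tsv()]; columns `rt_min`, `mz`, `im_1k0`,
#' `intensity`, full double precision, `.` decimal mark.
#'
#' @param peaks Peak tibble (`rt`, `mz`, `im`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_tsv <- function(peaks, path) {
  validate_peaks(peaks)
  out <- data.frame(rt_min = format_num(peaks$rt), mz = format_num(peaks$mz),
                    im_1k0 = format_num(peaks$im),
                    intensity = format_num(peaks$intensity))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# full-precision, locale-independent numeric formatting for TSV output
format_num <- function(x) {
  formatC(x, format = "g", digits = 17, mode = "double")
}

new_run_peaks <- function(x, run_id) {
  x <- as_tibble(x)
  attr(x, "run_id") <- run_id
  x
}

#' Run label of a peak tibble
#' @param peaks A peak tibble produced by one of the readers or the
#'   synthetic generator.
#' @return The run id string, or `NA` if none was attached.
#' @export
run_id <- function(peaks) {
  rid <- attr(peaks, "run_id", exact = TRUE)
  if (is.null(rid)) NA_character_ else rid
}

#' Scan-cycle retention-time grid of a run
#'
#' The sorted distinct retention times of a run's peaks, one entry per scan
#' cycle. Readers never reorder it: it is ascending regardless of input
#' row order.
#'
#' @param peaks Peak tibble.
#' @return Sorted numeric vector of retention times (minutes).
#' @export
rt_grid <- function(peaks) {
  sort(unique(peaks$rt))
}

validate_peaks <- function(x, source = "peak data") {
  need <- c("rt", "mz", "im", "intensity")
  if (!all(need %in% names(x))) {
    abort(paste0(source, ": expected columns rt, mz, im, intensity"),
          class = "lfq4d_format_error")
  }
  bad <- which(x$intensity < 0)
  if (length(bad)) {
    abort(paste0(source, ": negative intensity at data line ", bad[1]),
          class = "lfq4d_validation_error")
  }
  bad <- which(!(x$mz > 0) | !(x$im > 0) | x$rt < 0)
  if (length(bad)) {
    abort(paste0(source, ": invalid coordinates (need mz > 0, im > 0, ",
                 "rt >= 0) at data line ", bad[1]),
          class = "lfq4d_validation_error")
  }
  invisible(x)
}

#' Read an FDR-filtered PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches with columns
#' `run`, `spectrum`, `peptide`, `charge`, `theoretical_mz`, `rt_min`,
#' `im_1k0`, `protein` and optionally `organism`. Peptides carry
#' modifications inline as bracketed masses (e.g. `M[+15.9949]`); the ion
#' identity used downstream is the (modified peptide, charge) pair.
#' Multiple protein accessions are separated by `;` in the `protein`
#' column and kept as a single semicolon-joined string.
#'
#' @param path Path to the PSM TSV.
#' @return A tibble with columns `run_id`, `spectrum_id`, `peptide`,
#'   `charge`, `theoretical_mz`, `rt`, `im`, `proteins`, `organism`.
#' @export
read_psm_table <- function(path) {
  stopifnot(file.exists(path))
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  required <- c("run", "spectrum", "peptide", "charge", "theoretical_mz",
                "rt_min", "im_1k0", "protein")
  missing_col <- setdiff(required, hdr)
  if (length(missing_col)) {
    abort(paste0("PSM table ", path, " is missing required column(s): ",
                 paste(missing_col, collapse = ", ")),
          class = "lfq4d_format_error")
  }
  x <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, locale = readr::locale(decimal_mark = "."))
  x$theoretical_mz <- as.numeric(x$theoretical_mz)
  x$rt_min <- as.numeric(x$rt_min)
  x$im_1k0 <- as.numeric(x$im_1k0)
  charge <- suppressWarnings(as.integer(x$charge))
  bad <- which(is.na(charge) | charge <= 0)
  if (length(bad)) {
    abort(paste0("PSM table ", path, ": charge must be a positive integer ",
                 "(data line ", bad[1], ": '", x$charge[bad[1]], "')"),
          class = "lfq4d_validation_error")
  }
  bad <- which(!(x$theoretical_mz > 0))
  if (length(bad)) {
    abort(paste0("PSM table ", path, ": theoretical_mz must be positive ",
                 "(data line ", bad[1], ")"),
          class = "lfq4d_validation_error")
  }
  bad <- which(is.na(x$peptide) | x$peptide == "")
  if (length(bad)) {
    abort(paste0("PSM table ", path, ": empty peptide at data line ", bad[1]),
          class = "lfq4d_validation_error")
  }
  tibble(
    run_id = x$run, spectrum_id = x$spectrum, peptide = x$peptide,
    charge = charge, theoretical_mz = x$theoretical_mz,
    rt = x$rt_min, im = x$im_1k0, proteins = x$protein,
    organism = if ("organism" %in% names(x)) x$organism else NA_character_
  )
}

#' Split a semicolon-joined protein string into accessions
#' @param proteins Character vector of `;`-separated accession strings.
#' @return A list of character vectors, one per input element.
#' @export
split_proteins <- function(proteins) {
  strsplit(proteins, ";", fixed = TRUE)
}

#' Write a PSM table to TSV
#' @param psms PSM tibble as returned by [read_psm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- data.frame(
    run = psms$run_id, spectrum = psms$spectrum_id, peptide = psms$peptide,
    charge = psms$charge, theoretical_mz = format_num(psms$theoretical_mz),
    rt_min = format_num(psms$rt), im_1k0 = format_num(psms$im),
    protein = psms$proteins,
    organism = if ("organism" %in% names(psms)) psms$organism
               else NA_character_
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an experiment design table
#'
#' TSV with columns `run`, `condition`, `replicate`, one row per run.
#'
#' @param path Path to the design TSV.
#' @return Tibble with columns `run_id`, `condition`, `replicate`.
#' @export
read_design <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    run = readr::col_character(), condition = readr::col_character(),
    replicate = readr::col_character()
  ), progress = FALSE)
  if (anyDuplicated(x$run)) {
    abort("experiment design: duplicate run id",
          class = "lfq4d_validation_error")
  }
  tibble(run_id = x$run, condition = x$condition, replicate = x$replicate)
}

#' Write an experiment design table
#' @param design Tibble with `run_id`, `condition`, `replicate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(
    data.frame(run = design$run_id, condition = design$condition,
               replicate = design$replicate),
    path, progress = FALSE)
  invisible(path)
}
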