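# Versioned binary peak cache. Layout (little-endian):
#   8 bytes  magic "LFQ4DPKC"
#   int32    format version
#   int32    run_id byte length, then raw UTF-8 run_id
#   int32    number of peaks n
#   4 * n    doubles: rt, mz, im, intensity (column blocks)
CACHE_MAGIC <- charToRaw("LFQ4DPKC")
CACHE_VERSION <- 1L

#' Write a binary peak cache
#'
#' Stores a run's peaks in a compact versioned binary format so later
#' analyses can skip TSV/mzML parsing. Reading back a cache reproduces the
#' written peaks exactly (doubles round-trip bit-for-bit). Files written by
#' a different format version are refused, never silently reused.
#'
#' @param peaks Peak tibble (`rt`, `mz`, `im`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cache <- function(peaks, path) {
  validate_peaks(peaks)
  rid <- run_id(peaks)
  if (is.na(rid)) rid <- ""
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CACHE_MAGIC, con)
  writeBin(CACHE_VERSION, con, size = 4L, endian = "little")
  rid_raw <- charToRaw(enc2utf8(rid))
  writeBin(length(rid_raw), con, size = 4L, endian = "little")
  writeBin(rid_raw, con)
  writeBin(nrow(peaks), con, size = 4L, endian = "little")
  for (col in c("rt", "mz", "im", "intensity")) {
    writeBin(as.double(peaks[[col]]), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a binary peak cache
#'
#' @param path Path to a file written by [write_cache()].
#' @return A peak tibble identical to the one written.
#' @export
read_cache <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(CACHE_MAGIC))
  if (length(magic) < length(CACHE_MAGIC) || !identical(magic, CACHE_MAGIC)) {
    abort(paste0(path, " is not an lfq4d peak cache (bad magic bytes)"),
          class = "lfq4d_cache_error")
  }
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(version, CACHE_VERSION)) {
    abort(paste0(path, ": incompatible cache format version ", version,
                 " (this build reads version ", CACHE_VERSION, "); ",
                 "regenerate the cache"),
          class = "lfq4d_cache_error")
  }
  rid_len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  rid <- if (rid_len > 0) {
    rawToChar(readBin(con, "raw", n = rid_len))
  } else ""
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  cols <- lapply(1:4, function(i) {
    v <- readBin(con, "double", n = n, size = 8L, endian = "little")
    if (length(v) != n) {
      abort(paste0(path, ": truncated cache file"),
            class = "lfq4d_cache_error")
    }
    v
  })
  x <- tibble(rt = cols[[1]], mz = cols[[2]], im = cols[[3]],
              intensity = cols[[4]])
  new_run_peaks(x, if (nzchar(rid)) rid else NA_character_)
}
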