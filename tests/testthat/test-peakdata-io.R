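test_that("peak TSV round-trips, preserves order, and sorts the RT grid", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tmz\tim_1k0\tintensity",
               "10.1\t500.2\t0.91\t800",
               "10.0\t500.1\t0.90\t1200",
               "10.0\t499.9\t0.92\t700"), p)
  x <- read_peak_tsv(p, run_id = "r1")
  expect_equal(nrow(x), 3)
  expect_equal(run_id(x), "r1")
  expect_equal(rt_grid(x), c(10.0, 10.1))
  expect_equal(x$mz, c(500.2, 500.1, 499.9))  # input row order kept

  # write -> read is identity on arbitrary generated peaks
  pk <- random_run(1000, seed = 42)
  attr(pk, "run_id") <- "gen"
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_peak_tsv(pk, p2)
  back <- read_peak_tsv(p2, run_id = "gen")
  expect_equal(back$rt, pk$rt)
  expect_equal(back$mz, pk$mz)
  expect_equal(back$im, pk$im)
  expect_equal(back$intensity, pk$intensity)
})

test_that("peak TSV reader validates header and values", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tmz\tintensity", "1\t2\t3"), p)
  expect_error(read_peak_tsv(p), "im_1k0", class = "lfq4d_format_error")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tmz\tim_1k0\tintensity",
               "10.0\t500.1\t0.90\t1200",
               "10.1\t500.1\t0.90\t-5"), p2)
  expect_error(read_peak_tsv(p2), "line 2",
               class = "lfq4d_validation_error")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rt_min\tmz\tim_1k0\tintensity", p3)
  empty <- read_peak_tsv(p3)
  expect_equal(nrow(empty), 0)
  expect_length(rt_grid(empty), 0)
})

test_that("binary cache round-trips exactly and refuses foreign files", {
  pk <- random_run(5000, seed = 7)
  attr(pk, "run_id") <- "cached_run"
  p <- withr::local_tempfile(fileext = ".pkc")
  write_cache(pk, p)
  back <- read_cache(p)
  expect_identical(back$rt, pk$rt)        # bit-for-bit double round trip
  expect_identical(back$mz, pk$mz)
  expect_identical(back$im, pk$im)
  expect_identical(back$intensity, pk$intensity)
  expect_equal(run_id(back), "cached_run")

  # corrupted magic bytes
  raw <- readBin(p, "raw", n = file.size(p))
  raw[2] <- as.raw(0)
  p_bad <- withr::local_tempfile(fileext = ".pkc")
  writeBin(raw, p_bad)
  expect_error(read_cache(p_bad), "magic", class = "lfq4d_cache_error")

  # version bump is refused, never silently reused
  raw2 <- readBin(p, "raw", n = file.size(p))
  raw2[9] <- as.raw(99)
  p_v <- withr::local_tempfile(fileext = ".pkc")
  writeBin(raw2, p_v)
  expect_error(read_cache(p_v), "version", class = "lfq4d_cache_error")
})

test_that("cache reads faster than re-parsing the TSV it came from", {
  pk <- random_run(1e5, seed = 9)
  attr(pk, "run_id") <- "big"
  tsv <- withr::local_tempfile(fileext = ".tsv")
  pkc <- withr::local_tempfile(fileext = ".pkc")
  write_peak_tsv(pk, tsv)
  write_cache(pk, pkc)
  t_tsv <- system.time(read_peak_tsv(tsv))[["elapsed"]]
  t_pkc <- system.time(read_cache(pkc))[["elapsed"]]
  expect_lte(t_pkc, t_tsv + 0.05)  # non-regression, not a hard constant
})

test_that("PSM tables parse, split proteins, and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("run", "spectrum", "peptide", "charge", "theoretical_mz",
          "rt_min", "im_1k0", "protein", sep = "\t"),
    paste("r1", "r1.001", "PEPTIDEK", "2", "450.7301", "10.5", "0.92",
          "P1;P2", sep = "\t"),
    paste("r1", "r1.002", "M[+15.9949]AGICK", "3", "301.2", "11.0",
          "0.85", "P3", sep = "\t")), p)
  x <- read_psm_table(p)
  expect_equal(nrow(x), 2)
  expect_equal(x$peptide[2], "M[+15.9949]AGICK")
  expect_equal(split_proteins(x$proteins)[[1]], c("P1", "P2"))
  expect_equal(x$charge, c(2L, 3L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("run", "spectrum", "peptide", "charge", "theoretical_mz",
          "rt_min", "im_1k0", "protein", sep = "\t"),
    paste("r1", "r1.001", "PEPTIDEK", "0", "450.7", "10.5", "0.92", "P1",
          sep = "\t")), bad)
  expect_error(read_psm_table(bad), "line 1",
               class = "lfq4d_validation_error")

  # generator export re-read equals the in-memory records
  sim <- make_design(three_organism = FALSE, n_proteins = 4, seed = 5)
  r <- simulate_run(sim, "A", 1, sim_config(seed = 5, n_decoy_peaks = 0))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(r$psms, p2)
  back <- read_psm_table(p2)
  expect_equal(back$peptide, r$psms$peptide)
  expect_equal(back$theoretical_mz, r$psms$theoretical_mz)
  expect_equal(back$rt, r$psms$rt)
  expect_equal(back$proteins, r$psms$proteins)
})

test_that("experiment design reader enforces unique runs", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("run\tcondition\treplicate", "r1\tA\t1", "r1\tA\t2"), p)
  expect_error(read_design(p), "duplicate",
               class = "lfq4d_validation_error")
})

test_that("mzML export re-reads to the identical peak set", {
  pk <- random_run(300, seed = 21)
  attr(pk, "run_id") <- "mz_run"
  p <- withr::local_tempfile(fileext = ".mzML")
  write_mzml_im(pk, p)
  back <- read_mzml_im(p, run_id = "mz_run")
  expect_equal(nrow(back), nrow(pk))
  # reader groups by spectrum: compare as sorted multisets
  key <- function(d) order(d$rt, d$mz, d$im, d$intensity)
  a <- pk[key(pk), ]
  b <- back[key(back), ]
  expect_equal(b$rt, a$rt, tolerance = 1e-9)
  expect_equal(b$mz, a$mz, tolerance = 1e-9)
  expect_equal(b$im, a$im, tolerance = 1e-9)
  expect_equal(b$intensity, a$intensity, tolerance = 1e-9)
  expect_equal(length(rt_grid(back)), length(rt_grid(pk)))
})

test_that("spectrum-level mobility values are expanded per peak", {
  b64 <- function(x) {
    gsub("[\r\n]", "", jsonlite::base64_enc(
      writeBin(as.double(x), raw(), size = 8L, endian = "little")))
  }
  arr <- function(x, acc, name) {
    paste0('<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523"',
           ' name="64-bit float"/><cvParam cvRef="MS" accession="',
           acc, '" name="', name, '"/><binary>', b64(x),
           '</binary></binaryDataArray>')
  }
  spec <- function(i, rt, im, mzs, ints) {
    paste0('<spectrum index="', i, '" defaultArrayLength="3">',
           '<cvParam cvRef="MS" accession="MS:1000511" name="ms level"',
           ' value="1"/>',
           '<scanList count="1"><scan>',
           '<cvParam cvRef="MS" accession="MS:1000016"',
           ' name="scan start time" value="', rt,
           '" unitName="minute"/>',
           '<cvParam cvRef="MS" accession="MS:1002815"',
           ' name="inverse reduced ion mobility" value="', im, '"/>',
           '</scan></scanList><binaryDataArrayList count="2">',
           arr(mzs, "MS:1000514", "m/z array"),
           arr(ints, "MS:1000515", "intensity array"),
           '</binaryDataArrayList></spectrum>')
  }
  doc <- paste0('<mzML><run id="r"><spectrumList count="2">',
                spec(0, 10.0, 0.91, c(400, 500, 600), c(1, 2, 3)),
                spec(1, 10.1, 0.95, c(410, 510, 610), c(4, 5, 6)),
                '</spectrumList></run></mzML>')
  p <- withr::local_tempfile(fileext = ".mzML")
  writeLines(doc, p)
  x <- read_mzml_im(p, run_id = "r")
  expect_equal(nrow(x), 6)
  expect_equal(rt_grid(x), c(10.0, 10.1))
  expect_equal(x$im, rep(c(0.91, 0.95), each = 3))
  expect_equal(x$mz[1:3], c(400, 500, 600))
})

test_that("mzML reader flags missing mobility and ignores MS2", {
  pk <- random_run(10, seed = 3)
  attr(pk, "run_id") <- "r"
  p <- withr::local_tempfile(fileext = ".mzML")
  write_mzml_im(pk, p)
  txt <- readLines(p)
  # strip the mobility arrays -> unsupported input
  stripped <- gsub(
    paste0('<binaryDataArray[^>]*><cvParam[^/]*/><cvParam[^/]*/>',
           '<cvParam[^>]*MS:1002816[^>]*/><binary>[^<]*</binary>',
           '</binaryDataArray>'),
    "", paste(txt, collapse = "\n"))
  p2 <- withr::local_tempfile(fileext = ".mzML")
  writeLines(stripped, p2)
  expect_error(read_mzml_im(p2), "mobility",
               class = "lfq4d_unsupported_input")

  # MS2-only file: zero peaks with a warning
  ms2 <- gsub('name="ms level" value="1"', 'name="ms level" value="2"',
              paste(txt, collapse = "\n"))
  p3 <- withr::local_tempfile(fileext = ".mzML")
  writeLines(ms2, p3)
  expect_warning(x <- read_mzml_im(p3), "MS1")
  expect_equal(nrow(x), 0)

  p4 <- withr::local_tempfile(fileext = ".mzML")
  writeLines("<mzML><oops", p4)
  expect_error(read_mzml_im(p4), class = "lfq4d_format_error")
})

test_that("exported mzML is readable by an independent mzML parser", {
  skip_if_not_installed("mzR")
  pk <- random_run(50, seed = 13, n_cycles = 5)
  attr(pk, "run_id") <- "xcheck"
  p <- withr::local_tempfile(fileext = ".mzML")
  write_mzml_im(pk, p)
  h <- suppressWarnings(mzR::openMSfile(p))
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  expect_equal(nrow(hdr), length(rt_grid(pk)))
  pks <- mzR::peaks(h)
  got_mz <- sort(unlist(lapply(pks, function(m) m[, 1])))
  expect_equal(got_mz, sort(pk$mz), tolerance = 1e-9)
})

test_that("pepXML reader recovers peptide, charge, m/z, and proteins", {
  p <- withr::local_tempfile(fileext = ".pepXML")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<msms_pipeline_analysis>',
    '<msms_run_summary base_name="/data/runA">',
    '<spectrum_query spectrum="runA.00001.2" assumed_charge="2"',
    ' retention_time_sec="630.0" ion_mobility="0.95">',
    '<search_result><search_hit hit_rank="1" peptide="ELVISK"',
    ' protein="P1" calc_neutral_pep_mass="701.4061">',
    '<alternative_protein protein="P2"/>',
    '</search_hit></search_result></spectrum_query>',
    '<spectrum_query spectrum="runA.00002.2" assumed_charge="2"',
    ' retention_time_sec="660.0" ion_mobility="0.88">',
    '<search_result><search_hit hit_rank="1" peptide="MAGICK"',
    ' protein="P3" calc_neutral_pep_mass="679.3266">',
    '<modification_info>',
    '<mod_aminoacid_mass position="1" mass="147.0354"/>',
    '</modification_info>',
    '</search_hit></search_result></spectrum_query>',
    '</msms_run_summary></msms_pipeline_analysis>'), p)
  x <- read_pepxml(p)
  expect_equal(nrow(x), 2)
  expect_equal(x$run_id, c("runA", "runA"))
  expect_equal(x$peptide[1], "ELVISK")
  expect_equal(x$peptide[2], "M[147.0354]AGICK")
  expect_equal(x$proteins[1], "P1;P2")
  expect_equal(x$rt[1], 10.5)
  expect_equal(x$im[2], 0.88)
  expect_equal(x$theoretical_mz[1], (701.4061 + 2 * 1.00727646688) / 2,
               tolerance = 1e-9)
})
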