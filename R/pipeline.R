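# End-to-end orchestration: quantify -> normalize -> roll up -> report,
# with reproducible outputs and a run log naming the config hash.

#' Quantify a multi-run experiment end to end
#'
#' Runs the full pipeline: per run, build the 4-D index and quantify every
#' distinct PSM-identified ion; merge runs into the ion matrix; piecewise
#' normalization (unless disabled); protein roll-up; MSstats export; and,
#' for two-condition designs, the per-organism ratio summary. Identical
#' inputs and configuration produce identical outputs.
#'
#' @param peaks Named list of peak tibbles (names = run ids) or a named
#'   character vector of peak-table paths (TSV via [read_peak_tsv()],
#'   `.mzML` via [read_mzml_im()], cache files via [read_cache()]).
#' @param psms A PSM tibble covering all runs, or a path to a PSM TSV.
#' @param design A design tibble (`run_id`, `condition`, `replicate`) or a
#'   path to a design TSV.
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output and returns results in memory only.
#' @param config A [pipeline_config()].
#' @param normalize Override for `config$norm$enabled`.
#' @return Invisibly, a list: `ion_records` (per run), `matrix`
#'   (normalized `ion_matrix`), `raw_matrix`, `norm_model`, `proteins`,
#'   `ratio_summary` (or `NULL`), `paths` (written files).
#' @export
run_quantify <- function(peaks, psms, design, out_dir = NULL,
                         config = pipeline_config(), normalize = NULL) {
  if (is.character(design)) design <- read_design(design)
  if (is.character(psms)) psms <- read_psm_table(psms)
  if (is.character(peaks)) {
    paths <- peaks
    peaks <- lapply(paths, read_peaks_any)
    names(peaks) <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
      names(paths) else vapply(peaks, run_id, character(1))
  }
  if (is.null(names(peaks)) || !all(nzchar(names(peaks)))) {
    abort("peaks must be a named list/vector (names = run ids)",
          class = "lfq4d_argument_error")
  }
  missing_runs <- setdiff(names(peaks), design$run_id)
  if (length(missing_runs)) {
    abort(paste0("stage design: runs not in design: ",
                 paste(missing_runs, collapse = ", ")),
          class = "lfq4d_argument_error")
  }
  if (!is.null(normalize)) config$norm$enabled <- isTRUE(normalize)
  out <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out_dir
  } else NULL
  written <- list()

  ion_records <- list()
  for (rid in names(peaks)) {
    idx <- build_peak_index(peaks[[rid]], config$quant$index, run_id = rid)
    run_psms <- psms[psms$run_id == rid, , drop = FALSE]
    ion_records[[rid]] <- quantify_run(idx, run_psms, config$quant)
    if (!is.null(out)) {
      p <- file.path(out, paste0("ion_", rid, ".csv"))
      write_run_csv(ion_records[[rid]], p)
      written[[paste0("ion_", rid)]] <- p
    }
  }
  raw_matrix <- merge_runs(ion_records, design)

  norm <- normalize_ion_matrix(raw_matrix, config$norm)
  matrix <- norm$matrix
  if (!is.null(out)) {
    p <- file.path(out, "ion_matrix.tsv")
    readr::write_tsv(as_tibble(matrix), p, progress = FALSE, na = "")
    written$ion_matrix <- p
    if (!is.null(norm$model)) {
      written$norm_report <- write_norm_report(
        norm$model, file.path(out, "normalization.tsv"))
    }
  }

  proteins <- rollup(matrix, config$rollup)
  ratio <- NULL
  if (length(unique(design$condition)) == 2) {
    ratio <- ratio_report(proteins)
  }
  if (!is.null(out)) {
    written$proteins <- write_protein_tsv(proteins,
                                          file.path(out, "proteins.tsv"))
    written$msstats <- export_msstats(matrix, design,
                                      path = file.path(out, "msstats.csv"))
    if (!is.null(ratio)) {
      written$ratio <- write_ratio_tsv(ratio,
                                       file.path(out, "ratio_summary.tsv"))
    }
    written$log <- write_run_log(out, config, design)
  }
  invisible(list(
    ion_records = ion_records, matrix = matrix, raw_matrix = raw_matrix,
    norm_model = norm$model, proteins = proteins, ratio_summary = ratio,
    paths = written))
}

read_peaks_any <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    read_mzml_im(path)
  } else if (grepl("\\.(pkc|cache|bin)$", path, ignore.case = TRUE)) {
    read_cache(path)
  } else {
    read_peak_tsv(path)
  }
}

write_run_log <- function(out, config, design, seed = NULL) {
  p <- file.path(out, "run_log.txt")
  writeLines(c(
    paste0("lfq4d version: ", as.character(utils::packageVersion("lfq4d"))),
    paste0("config hash: ", rlang::hash(config)),
    paste0("runs: ", paste(design$run_id, collapse = ", ")),
    if (!is.null(seed)) paste0("seed: ", seed),
    paste0("mz_tol_ppm: ", config$quant$index$mz_tol_ppm),
    paste0("rt_tol_min: ", config$quant$index$rt_tol_min),
    paste0("im_tol: ", config$quant$index$im_tol),
    paste0("im_bin_width: ", config$quant$index$im_bin_width),
    paste0("min_isotope_count: ", config$quant$min_isotope_count),
    paste0("normalization: ", config$norm$enabled),
    paste0("min_ions: ", config$rollup$min_ions),
    paste0("top_n: ", config$rollup$top_n),
    paste0("min_experiment_fraction: ",
           config$rollup$min_experiment_fraction)
  ), p)
  p
}

#' Simulate a dataset and write it to disk
#'
#' Thin wrapper over [make_design()], [simulate_experiment()], and
#' [write_simulation()] for scripted use; the written directory
#' round-trips through [run_quantify()].
#'
#' @param out_dir Output directory.
#' @param seed Random seed.
#' @param three_organism Use the three-organism two-condition benchmark.
#' @param n_proteins,ions_per_protein,n_replicates See [make_design()].
#' @param config A [sim_config()]; its seed is overridden by `seed`.
#' @param run_biases See [simulate_experiment()].
#' @return Invisibly, the `sim_experiment` (with `$paths` of written
#'   files).
#' @export
run_simulate <- function(out_dir, seed = 1L, three_organism = TRUE,
                         n_proteins = NULL, ions_per_protein = 3L,
                         n_replicates = 3L, config = sim_config(),
                         run_biases = NULL) {
  config$seed <- as.integer(seed)
  sim <- make_design(three_organism = three_organism,
                     n_proteins = n_proteins,
                     ions_per_protein = ions_per_protein,
                     n_replicates = n_replicates, seed = seed,
                     gradient_min = config$gradient_min)
  experiment <- simulate_experiment(sim, config, run_biases = run_biases)
  experiment$paths <- write_simulation(experiment, out_dir)
  invisible(experiment)
}

#' Quantify a simulated experiment in memory
#'
#' Convenience wrapper feeding a [simulate_experiment()] result straight
#' into [run_quantify()] without touching disk.
#'
#' @param experiment A `sim_experiment`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory, passed through.
#' @return The [run_quantify()] result list.
#' @export
quantify_experiment <- function(experiment, config = pipeline_config(),
                                out_dir = NULL) {
  run_quantify(experiment$runs, experiment$psms, experiment$design,
               out_dir = out_dir, config = config)
}
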