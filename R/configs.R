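#' Tolerance settings for the 4-D peak index
#'
#' Controls how peaks are binned in the ion-mobility dimension and which
#' tolerance windows index queries apply. The defaults are the standard
#' identification-directed quantification tolerances for TIMS PASEF data:
#' 10 ppm in m/z, 0.4 min in retention time, 0.05 1/K0 in ion mobility,
#' with a mobility bin width of 0.002 1/K0.
#'
#' @param im_bin_width Width of one ion-mobility bin (1/K0, Vs/cm2).
#' @param mz_tol_ppm Symmetric m/z tolerance in parts per million, applied
#'   relative to the query center.
#' @param rt_tol_min Retention-time tolerance (minutes); used as the
#'   half-width of the apex-search seed window around a PSM's retention time.
#' @param im_tol Ion-mobility tolerance (1/K0); exact window applied after
#'   bin preselection.
#' @return A list of class `index_config`.
#' @export
#' @examples
#' index_config(mz_tol_ppm = 20)
index_config <- function(im_bin_width = 0.002, mz_tol_ppm = 10,
                         rt_tol_min = 0.4, im_tol = 0.05) {
  stopifnot(im_bin_width > 0, mz_tol_ppm > 0, rt_tol_min > 0, im_tol > 0)
  structure(
    list(im_bin_width = im_bin_width, mz_tol_ppm = mz_tol_ppm,
         rt_tol_min = rt_tol_min, im_tol = im_tol),
    class = "index_config"
  )
}

#' Settings for XIC tracing, smoothing, and boundary detection
#'
#' @param smoothing_sigma_cycles Standard deviation of the Gaussian
#'   smoothing kernel, in scan cycles. The kernel is truncated at +/- 4
#'   sigma and renormalized to unit sum.
#' @param boundary_fraction Fraction of the (smoothed) apex intensity below
#'   which the peak is considered finished when walking outward from the
#'   apex.
#' @param max_gap_cycles Number of consecutive empty scan cycles tolerated
#'   while extending a trace beyond the seed window.
#' @return A list of class `trace_config`. Isotope spacing is fixed at the
#'   13C-12C mass difference (1.003355 Da) divided by charge and is not a
#'   tunable.
#' @export
trace_config <- function(smoothing_sigma_cycles = 1.0,
                         boundary_fraction = 0.01,
                         max_gap_cycles = 2L) {
  stopifnot(smoothing_sigma_cycles > 0,
            boundary_fraction > 0, boundary_fraction < 1,
            max_gap_cycles >= 0)
  structure(
    list(smoothing_sigma_cycles = smoothing_sigma_cycles,
         boundary_fraction = boundary_fraction,
         max_gap_cycles = as.integer(max_gap_cycles),
         isotope_spacing = C13_C12_DELTA),
    class = "trace_config"
  )
}

#' Settings for peptide-ion quantification
#'
#' @param min_isotope_count Minimum number of successfully traced isotope
#'   features (of the up-to-three targeted: 0, +1, +2) required before an
#'   ion intensity is reported; ions below the threshold get a missing
#'   intensity. Default 2.
#' @param index An [index_config()].
#' @param trace A [trace_config()].
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(min_isotope_count = 2L,
                         index = index_config(),
                         trace = trace_config()) {
  stopifnot(min_isotope_count >= 1, min_isotope_count <= 3,
            inherits(index, "index_config"), inherits(trace, "trace_config"))
  structure(
    list(min_isotope_count = as.integer(min_isotope_count),
         index = index, trace = trace),
    class = "quant_config"
  )
}

#' Settings for piecewise intensity normalization
#'
#' @param n_ranges Number of equal-count log-intensity ranges per run.
#' @param mad_multiplier Log-ratios farther than `mad_multiplier` raw median
#'   absolute deviations from the per-range median are excluded before the
#'   correction is taken as the median of the remainder.
#' @param enabled Logical; when `FALSE` the pipeline skips normalization.
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(n_ranges = 10L, mad_multiplier = 1.0, enabled = TRUE) {
  stopifnot(n_ranges >= 1, mad_multiplier > 0, is.logical(enabled))
  structure(
    list(n_ranges = as.integer(n_ranges), mad_multiplier = mad_multiplier,
         enabled = isTRUE(enabled)),
    class = "norm_config"
  )
}

#' Settings for protein roll-up
#'
#' @param min_ions Proteins with fewer distinct quantified ions (counting
#'   across all experiments) are discarded. Default 2.
#' @param top_n Number of highest-intensity eligible ions summed into the
#'   protein intensity. Default 3.
#' @param min_experiment_fraction An ion is eligible for roll-up when it is
#'   quantified in at least this fraction of experiments
#'   (condition x replicate). Default 0.5.
#' @return A list of class `rollup_config`.
#' @export
rollup_config <- function(min_ions = 2L, top_n = 3L,
                          min_experiment_fraction = 0.5) {
  stopifnot(min_ions >= 1, top_n >= 1,
            min_experiment_fraction > 0, min_experiment_fraction <= 1)
  structure(
    list(min_ions = as.integer(min_ions), top_n = as.integer(top_n),
         min_experiment_fraction = min_experiment_fraction),
    class = "rollup_config"
  )
}

#' Aggregate pipeline configuration
#'
#' Bundles the per-stage configurations used by [run_quantify()]. All
#' defaults mirror the standard identification-directed LFQ defaults:
#' 10 ppm m/z, 0.4 min RT, 0.05 1/K0 mobility tolerance, 0.002 1/K0 bins,
#' minimum isotope count 2, normalization on, protein minimum ions 2,
#' top 3 ions in at least 50% of experiments.
#'
#' @param index,trace,quant,norm,rollup Stage configurations; `quant` is
#'   rebuilt from `index`/`trace` when left `NULL`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(index = index_config(), trace = trace_config(),
                            quant = NULL, norm = norm_config(),
                            rollup = rollup_config()) {
  if (is.null(quant)) quant <- quant_config(index = index, trace = trace)
  stopifnot(inherits(quant, "quant_config"), inherits(norm, "norm_config"),
            inherits(rollup, "rollup_config"))
  structure(
    list(quant = quant, norm = norm, rollup = rollup),
    class = "pipeline_config"
  )
}

#' @export
print.index_config <- function(x, ...) {
  cat("<index_config> im_bin_width=", x$im_bin_width,
      " mz_tol_ppm=", x$mz_tol_ppm, " rt_tol_min=", x$rt_tol_min,
      " im_tol=", x$im_tol, "\n", sep = "")
  invisible(x)
}
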