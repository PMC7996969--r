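#' Plot the extracted ion chromatogram of one ion
#'
#' Traces the XIC at the given coordinates and draws the per-mobility-bin
#' retention-time profiles, with the smoothed curve overlaid.
#'
#' @param index A `peak_index`.
#' @param mz_center,im_center,rt_seed Extraction coordinates.
#' @param config A [trace_config()].
#' @return A ggplot, or `NULL` (with a message) when nothing was traced.
#' @export
plot_xic <- function(index, mz_center, im_center, rt_seed,
                     config = trace_config()) {
  traces <- trace_xic(index, mz_center, im_center, rt_seed, config)
  if (!nrow(traces)) {
    inform("no signal traced at these coordinates")
    return(invisible(NULL))
  }
  smoothed <- gaussian_smooth(traces, config$smoothing_sigma_cycles)
  ggplot2::ggplot(traces, ggplot2::aes(.data$rt, .data$intensity)) +
    ggplot2::geom_col(width = 0.8 * min(diff(sort(unique(traces$rt)))),
                      fill = "grey70") +
    ggplot2::geom_line(data = smoothed, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = rt_seed, linetype = 3) +
    ggplot2::facet_wrap(~im_bin, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "retention time (min)", y = "intensity",
                  title = sprintf("XIC at m/z %.4f, 1/K0 %.3f",
                                  mz_center, im_center)) +
    ggplot2::theme_minimal()
}

#' Plot replicate CV distributions per condition
#'
#' @param object A `protein_quant`.
#' @param ... Unused.
#' @return A ggplot of per-condition protein CV densities, with the
#'   median marked.
#' @export
#' @method autoplot protein_quant
autoplot.protein_quant <- function(object, ...) {
  cv_cols <- grep("^cv_", names(object), value = TRUE)
  d <- as_tibble(object)[, c("protein", cv_cols)] %>%
    tidyr::pivot_longer(all_of(cv_cols), names_to = "condition",
                        values_to = "cv") %>%
    mutate(condition = sub("^cv_", "", .data$condition)) %>%
    filter(!is.na(.data$cv))
  med <- d %>%
    group_by(.data$condition) %>%
    summarise(median_cv = median(.data$cv), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$cv, colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$median_cv,
                                     colour = .data$condition),
                        linetype = 2) +
    ggplot2::labs(x = "protein CV across replicates", y = "density",
                  colour = "condition") +
    ggplot2::theme_minimal()
}
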