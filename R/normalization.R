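# Piecewise intensity normalization against a reference run: per run,
# log-intensities are split into equal-count ranges and each range is
# shifted by the median of its MAD-filtered log-ratios to the reference.

#' Select the normalization reference run
#'
#' The run with the most quantified ions; ties break toward the earlier
#' run in design order.
#'
#' @param matrix An `ion_matrix`.
#' @return A run id.
#' @export
select_reference_run <- function(matrix) {
  runs <- matrix_runs(matrix)
  if (!length(runs)) abort("empty ion matrix",
                           class = "lfq4d_argument_error")
  counts <- vapply(runs, function(r) sum(!is.na(matrix[[r]])), integer(1))
  runs[which.max(counts)]   # which.max takes the first maximum
}

#' Fit the piecewise normalization model for one run
#'
#' Uses only ions quantified in both the run and the reference. Log-ratios
#' `r = log(run) - log(reference)` are computed per shared ion; the run's
#' own quantified log-intensities are split into `n_ranges` equal-count
#' (quantile) ranges; within each range the additive log-space correction
#' is the median of the log-ratios lying within `mad_multiplier` raw
#' median absolute deviations of the range's median log-ratio. Ranges with
#' fewer than 3 shared ions inherit the global (equally MAD-filtered)
#' median correction.
#'
#' @param matrix An `ion_matrix`.
#' @param run Run id to fit.
#' @param reference Reference run id.
#' @param config A [norm_config()].
#' @return A tibble of class `norm_model`: `run_id`, `range`, `lo`, `hi`
#'   (natural-log intensity boundaries; outer boundaries infinite),
#'   `n_shared`, `correction` (natural log). Attribute `reference` holds
#'   the reference run id.
#' @export
fit_piecewise <- function(matrix, run, reference, config = norm_config()) {
  stopifnot(run %in% matrix_runs(matrix), reference %in% matrix_runs(matrix))
  x <- matrix[[run]]
  y <- matrix[[reference]]
  quantified <- !is.na(x)
  shared <- quantified & !is.na(y)
  n_ranges <- config$n_ranges
  # equal-count range boundaries from the run's own log-intensities
  lx <- log(x[quantified])
  if (length(lx) >= 2 && n_ranges > 1) {
    inner <- quantile(lx, probs = seq_len(n_ranges - 1) / n_ranges,
                      names = FALSE, type = 7)
  } else {
    inner <- numeric(0)
    n_ranges <- 1L
  }
  bounds <- c(-Inf, inner, Inf)
  model <- tibble(
    run_id = run, range = seq_len(n_ranges),
    lo = bounds[-length(bounds)], hi = bounds[-1],
    n_shared = 0L, correction = 0
  )
  if (!any(shared)) {
    warn(paste0("run ", run, " shares no quantified ions with reference ",
                reference, "; identity normalization"))
    return(new_norm_model(model, reference))
  }
  r <- log(x[shared]) - log(y[shared])
  lshared <- log(x[shared])
  filtered_median <- function(v, mult) {
    med <- median(v)
    dev <- mad(v, constant = 1)          # raw MAD, no normal scaling
    keep <- abs(v - med) <= mult * dev
    if (!any(keep)) med else median(v[keep])
  }
  global_corr <- filtered_median(r, config$mad_multiplier)
  rng <- findInterval(lshared, bounds, rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (k in seq_len(n_ranges)) {
    rk <- r[rng == k]
    model$n_shared[k] <- length(rk)
    model$correction[k] <- if (length(rk) >= 3) {
      filtered_median(rk, config$mad_multiplier)
    } else {
      global_corr
    }
  }
  new_norm_model(model, reference)
}

new_norm_model <- function(x, reference) {
  attr(x, "reference") <- reference
  class(x) <- c("norm_model", class(x))
  x
}

#' Fit normalization models for every non-reference run
#'
#' @param matrix An `ion_matrix`.
#' @param config A [norm_config()].
#' @param reference Reference run id; defaults to
#'   [select_reference_run()].
#' @return A `norm_model` tibble covering all non-reference runs
#'   (row-bound per-run models, attribute `reference`).
#' @export
fit_normalization <- function(matrix, config = norm_config(),
                              reference = NULL) {
  if (is.null(reference)) reference <- select_reference_run(matrix)
  runs <- setdiff(matrix_runs(matrix), reference)
  models <- lapply(runs, fit_piecewise, matrix = matrix,
                   reference = reference, config = config)
  new_norm_model(bind_rows(models), reference)
}

#' Apply a piecewise normalization model to an ion matrix
#'
#' Each quantified cell's log-intensity is reduced by its range's
#' correction and exponentiated back. The reference run is never altered;
#' missing cells stay missing. Cells below the first or above the last
#' boundary use the outermost range (boundaries are open-ended).
#'
#' @param matrix An `ion_matrix`.
#' @param models A `norm_model` from [fit_normalization()] (or row-bound
#'   [fit_piecewise()] fits).
#' @return The normalized `ion_matrix`.
#' @export
apply_normalization <- function(matrix, models) {
  reference <- attr(models, "reference", exact = TRUE)
  for (run in unique(models$run_id)) {
    if (identical(run, reference)) next
    m <- models[models$run_id == run, , drop = FALSE]
    x <- matrix[[run]]
    ok <- !is.na(x)
    if (!any(ok)) next
    bounds <- c(m$lo[1], m$hi)
    rng <- findInterval(log(x[ok]), bounds, rightmost.closed = TRUE,
                        all.inside = TRUE)
    x[ok] <- exp(log(x[ok]) - m$correction[rng])
    matrix[[run]] <- x
  }
  matrix
}

#' Normalize an ion matrix end to end
#'
#' Convenience wrapper: selects the reference run, fits all per-run
#' piecewise models, and applies them.
#'
#' @param matrix An `ion_matrix`.
#' @param config A [norm_config()]; when `enabled` is `FALSE` the matrix
#'   is returned untouched with a `NULL` model.
#' @return A list with elements `matrix` (normalized) and `model`.
#' @export
normalize_ion_matrix <- function(matrix, config = norm_config()) {
  if (!config$enabled) return(list(matrix = matrix, model = NULL))
  model <- fit_normalization(matrix, config)
  list(matrix = apply_normalization(matrix, model), model = model)
}

#' @export
#' @method tidy norm_model
tidy.norm_model <- function(x, ...) {
  tibble(
    run_id = x$run_id, range = x$range,
    lo_log10 = x$lo / log(10), hi_log10 = x$hi / log(10),
    n_shared = x$n_shared, correction_log2 = x$correction / log(2)
  )
}

#' @export
#' @method glance norm_model
glance.norm_model <- function(x, ...) {
  tibble(
    reference = attr(x, "reference", exact = TRUE),
    n_runs = length(unique(x$run_id)),
    n_ranges = max(x$range),
    max_abs_correction_log2 = max(abs(x$correction)) / log(2)
  )
}

#' Write the normalization report
#'
#' One row per (run, range): log10-intensity boundaries, number of ions
#' shared with the reference, and the log2 correction.
#'
#' @param model A `norm_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_norm_report <- function(model, path) {
  readr::write_tsv(tidy(model), path, progress = FALSE)
  invisible(path)
}

#' Plot piecewise normalization corrections
#'
#' @param object A `norm_model`.
#' @param ... Unused.
#' @return A ggplot: per-run step profile of log2 corrections across the
#'   log10-intensity ranges.
#' @export
#' @method autoplot norm_model
autoplot.norm_model <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(mid = (pmax(.data$lo_log10, min(.data$hi_log10) - 1) +
                    pmin(.data$hi_log10, max(.data$lo_log10) + 1)) / 2)
  ggplot2::ggplot(d, ggplot2::aes(.data$mid, .data$correction_log2,
                                  colour = .data$run_id)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "log10 intensity (range midpoint)",
                  y = "correction (log2)", colour = "run") +
    ggplot2::theme_minimal()
}
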