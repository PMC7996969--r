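# Protein roll-up, replicate statistics, MSstats export, and the
# multi-organism ratio benchmark report.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Missing values are dropped first; fewer than two remaining values give
#' `NA` (undefined, not an error).
#'
#' @param values Numeric vector of positive intensities.
#' @return A single non-negative number, or `NA`.
#' @export
#' @examples
#' compute_cv(c(90, 110))  # 0.1414214
compute_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  sd(v) / mean(v)
}

#' Roll peptide-ion intensities up to proteins
#'
#' Proteins with fewer distinct quantified ions than `min_ions` (counted
#' across all experiments) are discarded. Among the remainder, ions
#' quantified in at least `min_experiment_fraction` of the experiments
#' (condition x replicate cells) are eligible; the `top_n` by total
#' intensity across experiments are selected, and each experiment's
#' protein intensity is the sum of the selected ions' intensities present
#' in that experiment. Ions mapping to several proteins count toward every
#' one of them, and such proteins are flagged (`has_shared_ions`).
#'
#' @param matrix An `ion_matrix`.
#' @param config A [rollup_config()].
#' @return A tibble of class `protein_quant`: `protein`, `organism`,
#'   `n_quantified_ions`, `n_ions_used`, `has_shared_ions`, one intensity
#'   column per experiment (named `<condition>_<replicate>`), and one
#'   `cv_<condition>` column per condition (CV across that condition's
#'   replicates; `NA` with fewer than two values). Attribute `design`
#'   carries the experiment design.
#' @export
rollup <- function(matrix, config = rollup_config()) {
  design <- design_of(matrix)
  design$experiment <- paste(design$condition, design$replicate, sep = "_")
  experiments <- unique(design$experiment)
  n_exp <- length(experiments)

  long <- ion_matrix_long(matrix, drop_missing = TRUE) %>%
    mutate(experiment = paste(.data$condition, .data$replicate, sep = "_"))
  prot_ion <- long %>%
    mutate(protein = split_proteins(.data$proteins)) %>%
    tidyr::unnest("protein")

  # ion-level statistics within each protein
  ion_stats <- prot_ion %>%
    group_by(.data$protein, .data$ion) %>%
    summarise(
      n_exp_quantified = dplyr::n_distinct(.data$experiment),
      total_intensity = sum(.data$intensity),
      shared = dplyr::first(grepl(";", .data$proteins, fixed = TRUE)),
      organism = dplyr::first(.data$organism),
      .groups = "drop_last"
    )

  selected <- ion_stats %>%
    mutate(n_quantified_ions = n()) %>%
    filter(.data$n_quantified_ions >= config$min_ions) %>%
    filter(.data$n_exp_quantified / n_exp >=
             config$min_experiment_fraction) %>%
    arrange(desc(.data$total_intensity), .data$ion, .by_group = TRUE) %>%
    slice(seq_len(min(config$top_n, n()))) %>%
    ungroup()

  kept_proteins <- ion_stats %>%
    group_by(.data$protein) %>%
    summarise(n_quantified_ions = n(),
              has_shared_ions = any(.data$shared),
              organism = dplyr::first(.data$organism[!is.na(.data$organism)],
                                      default = NA_character_),
              .groups = "drop") %>%
    filter(.data$n_quantified_ions >= config$min_ions)

  per_exp <- selected %>%
    select(all_of(c("protein", "ion"))) %>%
    left_join(long %>% select(all_of(c("ion", "experiment", "intensity"))),
              by = "ion", relationship = "many-to-many") %>%
    group_by(.data$protein, .data$experiment) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "experiment",
                       values_from = "intensity")
  n_used <- selected %>%
    group_by(.data$protein) %>%
    summarise(n_ions_used = n(), .groups = "drop")

  out <- kept_proteins %>%
    left_join(n_used, by = "protein") %>%
    mutate(n_ions_used = ifelse(is.na(.data$n_ions_used), 0L,
                                .data$n_ions_used)) %>%
    left_join(per_exp, by = "protein")
  for (e in experiments) {
    if (!e %in% names(out)) out[[e]] <- NA_real_
  }
  out <- out[, c("protein", "organism", "n_quantified_ions", "n_ions_used",
                 "has_shared_ions", experiments)]
  # replicate precision per condition
  for (cond in unique(design$condition)) {
    cols <- unique(design$experiment[design$condition == cond])
    vals <- as.matrix(out[, cols, drop = FALSE])
    out[[paste0("cv_", cond)]] <- vapply(seq_len(nrow(out)), function(i) {
      compute_cv(vals[i, ])
    }, numeric(1))
  }
  attr(out, "design") <- design
  class(out) <- c("protein_quant", class(out))
  out
}

#' @export
#' @method glance protein_quant
glance.protein_quant <- function(x, ...) {
  design <- design_of(x)
  cvs <- unlist(x[, grep("^cv_", names(x)), drop = FALSE])
  tibble(
    n_proteins = nrow(x),
    n_experiments = length(unique(design$experiment)),
    median_cv = median(cvs, na.rm = TRUE)
  )
}

#' Write the combined protein table
#' @param table A `protein_quant`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_tsv <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE, na = "")
  invisible(path)
}

#' Export an MSstats-compatible ion-level CSV
#'
#' One data row per quantified (ion, run) cell, with the MS1 sentinel
#' convention for fragment-level columns (`FragmentIon` and
#' `ProductCharge` are `NA`) and label type `L`. The full (possibly
#' semicolon-joined) protein assignment is kept in `ProteinName`.
#'
#' @param matrix An `ion_matrix`.
#' @param design Experiment design covering every run of the matrix;
#'   defaults to the design attached to the matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_msstats <- function(matrix, design = NULL, path) {
  if (is.null(design)) design <- design_of(matrix)
  missing_runs <- setdiff(matrix_runs(matrix), design$run_id)
  if (length(missing_runs)) {
    abort(paste0("runs absent from design: ",
                 paste(missing_runs, collapse = ", ")),
          class = "lfq4d_argument_error")
  }
  long <- ion_matrix_long(matrix, drop_missing = TRUE)
  out <- tibble(
    ProteinName = long$proteins,
    PeptideSequence = long$peptide,
    PrecursorCharge = long$charge,
    FragmentIon = NA_character_,
    ProductCharge = NA_integer_,
    IsotopeLabelType = "L",
    Condition = long$condition,
    BioReplicate = long$replicate,
    Run = long$run_id,
    Intensity = long$intensity
  )
  readr::write_csv(out, path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Between-condition ratio report by organism
#'
#' For a two-condition design, computes each protein's
#' `log2(mean intensity in A / mean intensity in B)` over the experiments
#' where it is quantified (proteins missing in either condition are
#' excluded), then summarises per organism: protein count, median, and
#' interquartile range of the log2 ratios. In a mixed-proteome benchmark
#' the medians recover the programmed mixing ratios.
#'
#' @param table A `protein_quant`.
#' @param condition_a,condition_b Condition labels for the ratio
#'   numerator and denominator; default to the design's first and second
#'   condition.
#' @return A tibble of class `ratio_summary`: `organism`, `n_proteins`,
#'   `median_log2_ratio`, `iqr_log2_ratio`, `median_fold`. Attribute
#'   `per_protein` holds the per-protein ratios for plotting.
#' @export
ratio_report <- function(table, condition_a = NULL, condition_b = NULL) {
  design <- design_of(table)
  conditions <- unique(design$condition)
  if (length(conditions) != 2 &&
      (is.null(condition_a) || is.null(condition_b))) {
    abort("ratio_report requires exactly two conditions",
          class = "lfq4d_argument_error")
  }
  if (is.null(condition_a)) condition_a <- conditions[1]
  if (is.null(condition_b)) condition_b <- conditions[2]
  cols_a <- design$experiment[design$condition == condition_a]
  cols_b <- design$experiment[design$condition == condition_b]
  mean_if_any <- function(m) {
    v <- rowMeans(m, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    v
  }
  mean_a <- mean_if_any(as.matrix(table[, cols_a, drop = FALSE]))
  mean_b <- mean_if_any(as.matrix(table[, cols_b, drop = FALSE]))
  per_protein <- tibble(
    protein = table$protein, organism = table$organism,
    mean_a = mean_a, mean_b = mean_b,
    log2_ratio = log2(mean_a / mean_b)
  ) %>%
    filter(!is.na(.data$log2_ratio))
  summary <- per_protein %>%
    group_by(.data$organism) %>%
    summarise(
      n_proteins = n(),
      median_log2_ratio = median(.data$log2_ratio),
      iqr_log2_ratio = stats::IQR(.data$log2_ratio),
      .groups = "drop"
    ) %>%
    mutate(median_fold = 2^.data$median_log2_ratio)
  attr(summary, "per_protein") <- per_protein
  attr(summary, "conditions") <- c(condition_a, condition_b)
  class(summary) <- c("ratio_summary", class(summary))
  summary
}

#' @export
#' @method tidy ratio_summary
tidy.ratio_summary <- function(x, ...) {
  attr(x, "per_protein", exact = TRUE)
}

#' Write the ratio summary report
#' @param summary A `ratio_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_tsv <- function(summary, path) {
  readr::write_tsv(as_tibble(summary), path, progress = FALSE)
  invisible(path)
}

#' Benchmark-style ratio plot
#'
#' Scatter of per-protein log2 between-condition ratios against log10 mean
#' intensity, coloured by organism, with dashed lines at each organism's
#' median — the standard mixed-proteome benchmark view.
#'
#' @param object A `ratio_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot ratio_summary
autoplot.ratio_summary <- function(object, ...) {
  pp <- tidy(object) %>%
    mutate(log10_intensity = log10((.data$mean_a + .data$mean_b) / 2))
  conds <- attr(object, "conditions", exact = TRUE)
  ggplot2::ggplot(pp, ggplot2::aes(.data$log10_intensity,
                                   .data$log2_ratio,
                                   colour = .data$organism)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(
      data = as_tibble(object),
      mapping = ggplot2::aes(yintercept = .data$median_log2_ratio,
                             colour = .data$organism),
      linetype = 2) +
    ggplot2::labs(x = "log10 mean intensity",
                  y = paste0("log2(", conds[1], " / ", conds[2], ")"),
                  colour = "organism") +
    ggplot2::theme_minimal()
}
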