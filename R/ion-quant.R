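# Peptide-ion quantification: PSM-directed isotope extraction, per-run ion
# records, and assembly of the multi-run ion matrix.

#' Ion identity key of (modified peptide, charge)
#' @param peptide Modified peptide string (bracketed-mass modifications).
#' @param charge Charge state.
#' @return Character key, `"<peptide>/<charge>"`.
#' @export
ion_key <- function(peptide, charge) {
  paste0(peptide, "/", charge)
}

# Plain-vector quantification of one ion (hot path: no tibbles).
quantify_ion_raw <- function(index, mz, charge, im, rt_seed, config) {
  tcfg <- config$trace
  volumes <- c(NA_real_, NA_real_, NA_real_)
  apex_rt <- NA_real_
  apex_im <- NA_real_
  mono_idx <- NA_integer_
  for (k in 0:2) {
    f <- extract_feature_raw(index, mz + k * tcfg$isotope_spacing / charge,
                             im, rt_seed, tcfg)
    if (is.null(f)) {
      if (k == 0) break
      next
    }
    if (k == 0) {
      mono_idx <- f$apex_rt_idx
      apex_rt <- f$apex_rt
      apex_im <- f$apex_im
    } else if (abs(f$apex_rt_idx - mono_idx) > 1L) {
      next
    }
    volumes[k + 1L] <- f$volume
  }
  found <- !is.na(volumes) & volumes > 0
  n_iso <- sum(found)
  list(
    intensity = if (n_iso >= config$min_isotope_count) {
      sum(volumes[found])
    } else NA_real_,
    n_isotopes = n_iso, apex_rt = apex_rt, apex_im = apex_im)
}

#' Quantify one PSM's peptide ion
#'
#' Extracts up to three isotope features at the PSM's coordinates
#' ([extract_isotopes()]) and sums their volumes. The intensity is
#' reported only when at least `min_isotope_count` isotope features were
#' traced with positive volume; otherwise it is missing (`NA`) — missing
#' is a value, not an error.
#'
#' @param index A `peak_index` for the PSM's run.
#' @param psm A one-row PSM tibble (columns as from [read_psm_table()]).
#' @param config A [quant_config()].
#' @return A one-row ion-record tibble: `ion`, `peptide`, `charge`,
#'   `run_id`, `intensity`, `n_isotopes`, `apex_rt`, `apex_im`,
#'   `proteins`, `organism`.
#' @export
quantify_psm <- function(index, psm, config = quant_config()) {
  stopifnot(nrow(psm) == 1)
  q <- quantify_ion_raw(index, psm$theoretical_mz, psm$charge, psm$im,
                        psm$rt, config)
  tibble(
    ion = ion_key(psm$peptide, psm$charge),
    peptide = psm$peptide, charge = psm$charge, run_id = index$run_id,
    intensity = q$intensity, n_isotopes = q$n_isotopes,
    apex_rt = q$apex_rt, apex_im = q$apex_im,
    proteins = psm$proteins,
    organism = if ("organism" %in% names(psm)) psm$organism
               else NA_character_
  )
}

#' Quantify all peptide ions of one run
#'
#' PSMs sharing an ion key (modified peptide, charge) within a run are
#' collapsed before tracing: each distinct ion is quantified once, seeded
#' from its first PSM in table order. Returns one ion record per distinct
#' ion.
#'
#' @param index A `peak_index`.
#' @param psms PSM tibble for the same run.
#' @param config A [quant_config()].
#' @return An ion-record tibble, one row per distinct ion.
#' @export
quantify_run <- function(index, psms, config = quant_config()) {
  if (nrow(psms) && !all(psms$run_id == index$run_id)) {
    abort(paste0("PSM run ids do not match index run '", index$run_id, "'"),
          class = "lfq4d_argument_error")
  }
  seeds <- psms %>%
    mutate(ion = ion_key(.data$peptide, .data$charge)) %>%
    distinct(.data$ion, .keep_all = TRUE)
  n <- nrow(seeds)
  intensity <- numeric(n)
  n_isotopes <- integer(n)
  apex_rt <- numeric(n)
  apex_im <- numeric(n)
  mzs <- seeds$theoretical_mz
  charges <- seeds$charge
  ims <- seeds$im
  rts <- seeds$rt
  for (i in seq_len(n)) {
    q <- quantify_ion_raw(index, mzs[i], charges[i], ims[i], rts[i],
                          config)
    intensity[i] <- q$intensity
    n_isotopes[i] <- q$n_isotopes
    apex_rt[i] <- q$apex_rt
    apex_im[i] <- q$apex_im
  }
  tibble(
    ion = if (n) seeds$ion else character(),
    peptide = seeds$peptide, charge = seeds$charge,
    run_id = rep.int(index$run_id, n),
    intensity = intensity, n_isotopes = n_isotopes,
    apex_rt = apex_rt, apex_im = apex_im,
    proteins = seeds$proteins,
    organism = if ("organism" %in% names(seeds)) seeds$organism
               else rep(NA_character_, n)
  )
}

#' Merge per-run ion records into a multi-run ion matrix
#'
#' Builds the ions-by-runs intensity matrix as a wide tibble: one row per
#' ion key with its metadata (`peptide`, `charge`, `proteins`,
#' `organism`), one intensity column per run in design order. Ions not
#' quantified in a run are missing (`NA`), never zero.
#'
#' @param records An ion-record tibble ([quantify_run()] output for one or
#'   more runs, row-bound) or a list of such tibbles.
#' @param design Experiment design tibble (`run_id`, `condition`,
#'   `replicate`) covering every run present.
#' @return A tibble of class `ion_matrix` with attribute `design`. Run
#'   intensity columns are named by run id.
#' @export
merge_runs <- function(records, design) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- bind_rows(records)
  }
  if (anyDuplicated(design$run_id)) {
    abort("duplicate run_id in design", class = "lfq4d_argument_error")
  }
  extra <- setdiff(unique(records$run_id), design$run_id)
  if (length(extra)) {
    abort(paste0("runs absent from design: ", paste(extra, collapse = ", ")),
          class = "lfq4d_argument_error")
  }
  if (anyDuplicated(records[c("ion", "run_id")])) {
    abort("more than one record for an (ion, run) pair",
          class = "lfq4d_argument_error")
  }
  meta <- records %>%
    select(all_of(c("ion", "peptide", "charge", "proteins", "organism"))) %>%
    distinct(.data$ion, .keep_all = TRUE)
  wide <- records %>%
    select(all_of(c("ion", "run_id", "intensity"))) %>%
    filter(!is.na(.data$intensity)) %>%
    tidyr::pivot_wider(names_from = "run_id", values_from = "intensity")
  out <- left_join(meta, wide, by = "ion")
  for (rid in design$run_id) {        # every run gets a column, design order
    if (!rid %in% names(out)) out[[rid]] <- NA_real_
  }
  out <- out[, c("ion", "peptide", "charge", "proteins", "organism",
                 design$run_id)]
  new_ion_matrix(out, design)
}

new_ion_matrix <- function(x, design) {
  x <- as_tibble(x)
  attr(x, "design") <- design
  class(x) <- c("ion_matrix", class(x))
  x
}

#' Experiment design attached to an ion matrix or protein table
#' @param x An `ion_matrix` or `protein_quant` object.
#' @return The design tibble.
#' @export
design_of <- function(x) {
  d <- attr(x, "design", exact = TRUE)
  if (is.null(d)) abort("object carries no experiment design",
                        class = "lfq4d_argument_error")
  d
}

#' Run intensity columns of an ion matrix
#' @param matrix An `ion_matrix`.
#' @return Character vector of run ids (column names), in design order.
#' @export
matrix_runs <- function(matrix) {
  design_of(matrix)$run_id
}

#' Ion matrix in long (tidy) form
#'
#' @param matrix An `ion_matrix`.
#' @param drop_missing Drop (ion, run) cells with missing intensity.
#' @return Long tibble: `ion`, `peptide`, `charge`, `proteins`,
#'   `organism`, `run_id`, `intensity`, joined with the design's
#'   `condition` and `replicate`.
#' @export
ion_matrix_long <- function(matrix, drop_missing = FALSE) {
  design <- design_of(matrix)
  out <- matrix %>%
    as_tibble() %>%
    tidyr::pivot_longer(all_of(design$run_id), names_to = "run_id",
                        values_to = "intensity") %>%
    left_join(design, by = "run_id")
  if (drop_missing) out <- filter(out, !is.na(.data$intensity))
  out
}

#' Write one run's quantified ions to CSV
#'
#' One row per distinct ion of the run: ion key, charge, intensity
#' (missing when below the minimum isotope count), apex coordinates,
#' number of traced isotopes, and protein assignment.
#'
#' @param records Ion-record tibble for a single run.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(records, path) {
  readr::write_csv(
    records[, c("ion", "peptide", "charge", "intensity", "apex_rt",
                "apex_im", "n_isotopes", "proteins")],
    path, progress = FALSE, na = "")
  invisible(path)
}
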