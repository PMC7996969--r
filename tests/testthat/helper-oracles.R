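# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive expected behaviour from first principles (linear
# scans, explicit loops, exhaustive enumeration) so the indexed /
# vectorized implementations are checked against straight-line code.

# random peak cloud on a fixed scan grid
random_run <- function(n, seed, n_cycles = 60, rt_step = 0.1,
                       mz_range = c(300, 1300), im_range = c(0.6, 1.5)) {
  set.seed(seed)
  tibble::tibble(
    rt = sample.int(n_cycles, n, replace = TRUE) * rt_step,
    mz = runif(n, mz_range[1], mz_range[2]),
    im = runif(n, im_range[1], im_range[2]),
    intensity = rexp(n, rate = 1e-4)
  )
}

# linear-scan tolerance query: the defining triple condition, no index
brute_query <- function(peaks, cfg, mz_center, im_center, rt_lo, rt_hi) {
  keep <- abs(peaks$mz - mz_center) / mz_center * 1e6 <= cfg$mz_tol_ppm &
    abs(peaks$im - im_center) <= cfg$im_tol &
    peaks$rt >= rt_lo & peaks$rt <= rt_hi
  peaks[keep, , drop = FALSE]
}

# naive O(n * k) convolution with an independently built truncated
# Gaussian kernel
naive_gaussian_smooth <- function(x, sigma) {
  half <- as.integer(ceiling(4 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    wtot <- 0
    for (j in seq_along(offs)) {
      src <- i + offs[j]
      if (src >= 1 && src <= n) {
        s <- s + w[j] * x[src]
        wtot <- wtot + w[j]
      }
    }
    out[i] <- s / wtot   # kernel renormalized over in-range support
  }
  out
}

# exhaustive apex/boundary scan applying the documented rules with
# explicit loops
bounds_oracle <- function(rt, sm, rt_seed, rt_tol, frac) {
  in_win <- which(abs(rt - rt_seed) <= rt_tol)
  if (!length(in_win) || max(sm[in_win]) <= 0) return(NULL)
  best <- NULL
  for (i in in_win) {
    if (is.null(best)) {
      best <- i
    } else if (sm[i] > sm[best] ||
               (sm[i] == sm[best] &&
                (abs(rt[i] - rt_seed) < abs(rt[best] - rt_seed) ||
                 (abs(rt[i] - rt_seed) == abs(rt[best] - rt_seed) &&
                  rt[i] < rt[best])))) {
      best <- i
    }
  }
  thr <- frac * sm[best]
  hi <- length(sm)
  for (i in seq(best + 1, length.out = max(0, length(sm) - best))) {
    if (sm[i] < thr || sm[i] > sm[i - 1]) {
      hi <- i - 1
      break
    }
  }
  lo <- 1
  for (i in rev(seq_len(best - 1))) {
    if (sm[i] < thr || sm[i] > sm[i + 1]) {
      lo <- i + 1
      break
    }
  }
  list(apex = best, lo = lo, hi = hi)
}

# region growth on the raw peak list of one IM bin: start from the seed
# window and extend while occupied cycles continue within the gap limit
region_grow_oracle <- function(occupied_cycles, n_cycles, w_lo, w_hi,
                               max_gap) {
  occ <- rep(FALSE, n_cycles)
  occ[occupied_cycles] <- TRUE
  lo <- w_lo
  gap <- 0
  i <- w_lo - 1
  while (i >= 1) {
    if (occ[i]) {
      lo <- i
      gap <- 0
    } else {
      gap <- gap + 1
      if (gap > max_gap) break
    }
    i <- i - 1
  }
  hi <- w_hi
  gap <- 0
  i <- w_hi + 1
  while (i <= n_cycles) {
    if (occ[i]) {
      hi <- i
      gap <- 0
    } else {
      gap <- gap + 1
      if (gap > max_gap) break
    }
    i <- i + 1
  }
  c(lo, hi)
}

# exhaustive roll-up: eligibility, ranking, top-n selection, summation,
# all as literal loops over the protein's ions
rollup_oracle <- function(ion_values, min_ions, top_n, min_frac) {
  # ion_values: named list ion -> numeric vector over experiments (NA ok)
  quantified <- names(ion_values)[vapply(ion_values,
                                         function(v) any(!is.na(v)),
                                         logical(1))]
  if (length(quantified) < min_ions) return(NULL)
  n_exp <- length(ion_values[[1]])
  eligible <- character()
  for (ion in quantified) {
    if (sum(!is.na(ion_values[[ion]])) / n_exp >= min_frac) {
      eligible <- c(eligible, ion)
    }
  }
  totals <- vapply(ion_values[eligible],
                   function(v) sum(v, na.rm = TRUE), numeric(1))
  chosen <- eligible[order(-totals, eligible)][seq_len(min(top_n,
                                                           length(eligible)))]
  out <- numeric(n_exp)
  any_val <- rep(FALSE, n_exp)
  for (ion in chosen) {
    v <- ion_values[[ion]]
    for (e in seq_len(n_exp)) {
      if (!is.na(v[e])) {
        out[e] <- out[e] + v[e]
        any_val[e] <- TRUE
      }
    }
  }
  out[!any_val] <- NA_real_
  list(chosen = sort(chosen), intensities = out)
}

# build an ion matrix straight from per-run intensity vectors
make_test_matrix <- function(values, proteins = NULL, organism = NULL,
                             conditions = NULL) {
  # values: named list run_id -> named numeric vector (names = ions)
  runs <- names(values)
  ions <- unique(unlist(lapply(values, names)))
  if (is.null(proteins)) {
    proteins <- stats::setNames(paste0("P_", ions), ions)
  }
  if (is.null(organism)) {
    organism <- stats::setNames(rep(NA_character_, length(ions)), ions)
  }
  if (is.null(conditions)) conditions <- rep("A", length(runs))
  records <- dplyr::bind_rows(lapply(runs, function(r) {
    v <- values[[r]][ions]
    tibble::tibble(
      ion = ions, peptide = ions, charge = 2L, run_id = r,
      intensity = unname(v), n_isotopes = 2L,
      apex_rt = 10, apex_im = 1,
      proteins = unname(proteins[ions]),
      organism = unname(organism[ions])
    )
  }))
  records <- records[!is.na(records$intensity), ]
  design <- tibble::tibble(
    run_id = runs, condition = conditions,
    replicate = as.character(stats::ave(seq_along(runs), conditions,
                                        FUN = seq_along))
  )
  merge_runs(records, design)
}

# hand-built three-isotope single-ion run: mono/iso volumes 100/50/20
# at m/z 500 (z = 2), apex rt 10.3, im 0.9005
demo_isotope_peaks <- function(drop_isotopes = FALSE) {
  cycles <- seq(10.0, 10.6, by = 0.1)
  shape <- c(0, 20, 60, 20, 0, 0, 0)
  spacing <- 1.003355 / 2
  build <- function(mz, scale) {
    tibble::tibble(rt = cycles, mz = mz, im = 0.9005,
                   intensity = shape * scale)
  }
  peaks <- build(500.0, 1)
  if (!drop_isotopes) {
    peaks <- dplyr::bind_rows(peaks,
                              build(500.0 + spacing, 0.5),
                              build(500.0 + 2 * spacing, 0.2))
  }
  peaks <- peaks[peaks$intensity > 0 | peaks$mz == 500.0, ]
  attr(peaks, "run_id") <- "demo"
  peaks
}

demo_isotope_psm <- function() {
  tibble::tibble(
    run_id = "demo", spectrum_id = "demo.1", peptide = "PEPTIDEK",
    charge = 2L, theoretical_mz = 500.0, rt = 10.3, im = 0.9,
    proteins = "P1", organism = NA_character_
  )
}
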