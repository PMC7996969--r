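# XIC tracing, Gaussian smoothing, apex/boundary detection, IM clustering,
# and volume integration. Internal functions work on plain vectors for
# speed; the exported verbs wrap them in tibbles.

# ---- internal fast path ----------------------------------------------------

# Traces the RT dimension of every IM bin overlapping the mobility window.
# Returns a list of traces: list(bin, i0, rt, raw) where i0 is the rt_grid
# ordinal of the first trace point and raw the per-cycle summed intensity
# (zero-filled at unoccupied cycles inside the span).
trace_bins_raw <- function(index, mz_center, im_center, rt_seed, tcfg) {
  grid <- index$rt_grid
  n_grid <- length(grid)
  if (!n_grid) return(list())
  icfg <- index$config
  hits <- query_index_raw(index, mz_center, im_center, -Inf, Inf)
  if (!length(hits$rt)) return(list())
  # seed window on the scan-cycle grid
  w_lo <- bsearch_ge(grid, rt_seed - icfg$rt_tol_min)
  w_hi <- bsearch_gt(grid, rt_seed + icfg$rt_tol_min) - 1L
  if (w_lo > n_grid || w_hi < 1L || w_lo > w_hi) return(list())
  max_gap <- tcfg$max_gap_cycles
  by_bin <- split(seq_along(hits$im_bin), hits$im_bin)
  out <- vector("list", length(by_bin))
  n_out <- 0L
  all_idx <- hits$rt_idx
  all_val <- hits$intensity
  for (bi in seq_along(by_bin)) {
    sel <- by_bin[[bi]]
    bin <- hits$im_bin[sel[1L]]
    idx <- all_idx[sel]
    val <- all_val[sel]
    occ <- logical(n_grid)
    occ[idx] <- TRUE
    # per-cycle intensity sums (duplicates are few: loop accumulation)
    if (anyDuplicated(idx)) {
      acc <- numeric(n_grid)
      for (t in seq_along(idx)) acc[idx[t]] <- acc[idx[t]] + val[t]
      idx <- which(occ)
      val <- acc[idx]
    }
    lo <- w_lo
    gap <- 0L
    i <- w_lo - 1L
    while (i >= 1L) {
      if (occ[i]) {
        lo <- i; gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > max_gap) break
      }
      i <- i - 1L
    }
    hi <- w_hi
    gap <- 0L
    i <- w_hi + 1L
    while (i <= n_grid) {
      if (occ[i]) {
        hi <- i; gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > max_gap) break
      }
      i <- i + 1L
    }
    raw <- numeric(hi - lo + 1L)
    inside <- idx >= lo & idx <= hi
    if (!any(inside)) next
    raw[idx[inside] - lo + 1L] <- val[inside]
    n_out <- n_out + 1L
    out[[n_out]] <- list(bin = bin, i0 = lo, rt = grid[lo:hi], raw = raw)
  }
  out[seq_len(n_out)]
}

gauss_kernel <- function(sigma) {
  half <- as.integer(ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

smooth_vec <- function(x, sigma) {
  n <- length(x)
  if (!n) abort("cannot smooth an empty trace",
                class = "lfq4d_argument_error")
  kernel <- gauss_kernel(sigma)
  half <- (length(kernel) - 1L) %/% 2L
  if (n == 1L) return(x)  # unit-sum kernel leaves a single point unchanged
  padded <- c(numeric(half), x, numeric(half))
  # direct convolution sum; the kernel is symmetric, so no reversal
  # needed. Near the trace ends the kernel is renormalized over its
  # in-range support so a constant trace smooths to itself.
  num <- stats::embed(padded, length(kernel)) %*% kernel
  ones <- c(numeric(half), rep(1, n), numeric(half))
  den <- stats::embed(ones, length(kernel)) %*% kernel
  as.vector(num / den)
}

# Apex and boundary detection on a smoothed trace. Apex is the maximum
# within rt_tol of the seed (ties: closer to seed, then earlier RT);
# boundaries walk outward until the smoothed intensity drops below
# boundary_fraction * apex or rises again after descending (valley split).
# Returns list(apex, lo, hi, apex_int) of indices into the trace, or NULL
# when there is no signal in the seed window.
find_bounds_raw <- function(rt, sm, rt_seed, rt_tol, frac) {
  n <- length(sm)
  cand <- which(abs(rt - rt_seed) <= rt_tol)
  if (!length(cand) || all(sm[cand] <= 0)) return(NULL)
  smc <- sm[cand]
  mx <- max(smc)
  tied <- cand[smc == mx]
  apex <- if (length(tied) == 1L) {
    tied
  } else {
    # ties break toward the seed RT, then toward earlier RT
    tied[order(abs(rt[tied] - rt_seed), rt[tied])][1L]
  }
  thr <- frac * sm[apex]
  hi <- n
  i <- apex + 1L
  while (i <= n) {
    if (sm[i] < thr || sm[i] > sm[i - 1L]) {
      hi <- i - 1L
      break
    }
    i <- i + 1L
  }
  lo <- 1L
  i <- apex - 1L
  while (i >= 1L) {
    if (sm[i] < thr || sm[i] > sm[i + 1L]) {
      lo <- i + 1L
      break
    }
    i <- i - 1L
  }
  list(apex = apex, lo = lo, hi = hi, apex_int = sm[apex])
}

# Groups trace bins into maximal runs where consecutive occupied bins are
# at most `gap + 1` apart (i.e. allowing `gap` empty bins between members).
# Returns an integer component id per input bin.
bin_components <- function(bins, gap = 1L) {
  if (!length(bins)) return(integer())
  ord <- order(bins)
  sorted <- bins[ord]
  comp_sorted <- cumsum(c(1L, diff(sorted) > gap + 1L))
  comp <- integer(length(bins))
  comp[ord] <- comp_sorted
  comp
}

# Clusters traced-and-bounded IM bins into one 4-D feature anchored at the
# seed bin (the bin containing im_center, or the strongest trace if that
# bin is empty). Members must contain the seed apex RT within their own RT
# bounds and sit in the seed's adjacency component (one empty bin gap
# allowed). Volume sums raw intensities of member cycles inside the seed
# trace's RT bounds. Returns a one-row data frame or NULL.
cluster_raw <- function(traces, bounds, im_center, bin_width) {
  keep <- !vapply(bounds, is.null, logical(1))
  if (!any(keep)) return(NULL)
  traces <- traces[keep]
  bounds <- bounds[keep]
  bins <- vapply(traces, `[[`, integer(1), "bin")
  seed_bin <- as.integer(floor(im_center / bin_width))
  seed_i <- match(seed_bin, bins)
  if (is.na(seed_i)) {
    seed_i <- which.max(vapply(bounds, `[[`, numeric(1), "apex_int"))
  }
  sb <- bounds[[seed_i]]
  st <- traces[[seed_i]]
  apex_rt <- st$rt[sb$apex]
  rt_lo <- st$rt[sb$lo]
  rt_hi <- st$rt[sb$hi]
  # RT coherence with the seed apex, then mobility adjacency
  overlap <- vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]; bd <- bounds[[i]]
    tr$rt[bd$lo] <= apex_rt && apex_rt <= tr$rt[bd$hi]
  }, logical(1))
  traces <- traces[overlap]
  bounds <- bounds[overlap]
  bins <- bins[overlap]
  comp <- bin_components(bins, gap = 1L)
  si <- match(seed_bin, bins)
  if (is.na(si)) {
    # seed bin has no trace: anchor on the strongest surviving trace
    si <- which.max(vapply(bounds, `[[`, numeric(1), "apex_int"))
  }
  member <- comp == comp[si]
  traces <- traces[member]
  bounds <- bounds[member]
  bins <- bins[member]
  volume <- 0
  for (tr in traces) {
    in_rt <- tr$rt >= rt_lo & tr$rt <= rt_hi
    volume <- volume + sum(tr$raw[in_rt])
  }
  apex_w <- vapply(bounds, `[[`, numeric(1), "apex_int")
  bin_center <- (bins + 0.5) * bin_width
  list(
    apex_rt = apex_rt, rt_lo = rt_lo, rt_hi = rt_hi,
    apex_intensity = sb$apex_int,
    apex_rt_idx = st$i0 + sb$apex - 1L,
    im_lo = min(bins) * bin_width, im_hi = (max(bins) + 1L) * bin_width,
    apex_im = sum(bin_center * apex_w) / sum(apex_w),
    n_bins = length(bins), volume = volume
  )
}

# Full trace -> smooth -> bounds -> cluster chain at one m/z target.
extract_feature_raw <- function(index, mz_center, im_center, rt_seed, tcfg) {
  traces <- trace_bins_raw(index, mz_center, im_center, rt_seed, tcfg)
  if (!length(traces)) return(NULL)
  icfg <- index$config
  bounds <- lapply(traces, function(tr) {
    sm <- smooth_vec(tr$raw, tcfg$smoothing_sigma_cycles)
    find_bounds_raw(tr$rt, sm, rt_seed, icfg$rt_tol_min,
                    tcfg$boundary_fraction)
  })
  cluster_raw(traces, bounds, im_center, icfg$im_bin_width)
}

# ---- exported verbs --------------------------------------------------------

#' Trace extracted ion chromatograms through the 4-D index
#'
#' For every ion-mobility bin overlapping the mobility window around
#' `im_center`, builds the per-scan-cycle intensity trace at `mz_center`:
#' the trace covers the scan cycles within the retention-time tolerance of
#' `rt_seed` and is extended outward cycle by cycle for as long as matching
#' peaks continue (up to `max_gap_cycles` consecutive empty cycles).
#' Cycles with several matching peaks sum their intensities; empty cycles
#' inside the span are zero-filled. Bins with no matching signal yield no
#' rows.
#'
#' @param index A `peak_index`.
#' @param mz_center Target m/z (Th).
#' @param im_center Target ion mobility (1/K0).
#' @param rt_seed Seed retention time (minutes), e.g. a PSM's precursor RT.
#' @param config A [trace_config()].
#' @return A tibble with columns `im_bin`, `rt`, `intensity` (raw,
#'   unsmoothed), ordered by bin then retention time.
#' @export
trace_xic <- function(index, mz_center, im_center, rt_seed,
                      config = trace_config()) {
  traces <- trace_bins_raw(index, mz_center, im_center, rt_seed, config)
  if (!length(traces)) {
    return(tibble(im_bin = integer(), rt = double(), intensity = double()))
  }
  bind_rows(lapply(traces, function(tr) {
    tibble(im_bin = tr$bin, rt = tr$rt, intensity = tr$raw)
  }))
}

#' Gaussian-smooth an XIC trace
#'
#' Convolves the intensity sequence with a discrete Gaussian kernel
#' truncated at +/- 4 sigma and renormalized to unit sum. Output length
#' equals input length, and total intensity is conserved (to floating
#' point) whenever the signal does not touch the trace ends; at the ends
#' the kernel is renormalized over its in-range support, so a constant
#' trace smooths to itself. When the trace carries an `im_bin` column,
#' each bin is smoothed independently.
#'
#' @param trace A tibble with columns `rt` and `intensity` (optionally
#'   `im_bin`), as from [trace_xic()].
#' @param sigma_cycles Kernel standard deviation in scan cycles.
#' @return The trace tibble with `intensity` replaced by its smoothed
#'   values.
#' @export
gaussian_smooth <- function(trace, sigma_cycles = 1.0) {
  if (!nrow(trace)) {
    abort("cannot smooth an empty trace", class = "lfq4d_argument_error")
  }
  stopifnot(sigma_cycles > 0)
  if ("im_bin" %in% names(trace)) {
    trace %>%
      group_by(.data$im_bin) %>%
      mutate(intensity = smooth_vec(.data$intensity, sigma_cycles)) %>%
      ungroup()
  } else {
    mutate(trace, intensity = smooth_vec(.data$intensity, sigma_cycles))
  }
}

#' Locate the apex and boundaries of a smoothed trace
#'
#' The apex is the maximum-intensity point among trace points within the
#' retention-time tolerance of `rt_seed` (ties break toward the seed, then
#' toward earlier RT). Boundaries extend outward from the apex until the
#' smoothed intensity falls below `boundary_fraction` of the apex, rises
#' again after descending (valley split between overlapping peaks), or the
#' trace ends.
#'
#' @param trace A single-bin smoothed trace tibble (`rt`, `intensity`).
#' @param rt_seed Seed retention time (minutes).
#' @param config A [trace_config()].
#' @param rt_tol_min Apex search half-window (minutes).
#' @return A one-row tibble (`apex_rt`, `rt_lo`, `rt_hi`,
#'   `apex_intensity`), or a zero-row tibble when the trace has no signal
#'   within the seed window (a no-feature result, not an error).
#' @export
find_bounds <- function(trace, rt_seed, config = trace_config(),
                        rt_tol_min = 0.4) {
  if (!nrow(trace)) {
    abort("cannot locate bounds on an empty trace",
          class = "lfq4d_argument_error")
  }
  b <- find_bounds_raw(trace$rt, trace$intensity, rt_seed, rt_tol_min,
                       config$boundary_fraction)
  if (is.null(b)) {
    return(tibble(apex_rt = double(), rt_lo = double(), rt_hi = double(),
                  apex_intensity = double()))
  }
  tibble(apex_rt = trace$rt[b$apex], rt_lo = trace$rt[b$lo],
         rt_hi = trace$rt[b$hi], apex_intensity = b$apex_int)
}

#' Cluster per-bin traces into one 4-D feature
#'
#' Merges ion-mobility-adjacent traces (consecutive bin ordinals, one empty
#' bin gap allowed) whose retention-time bounds contain the seed trace's
#' apex into a single feature. The seed trace is the one in the bin
#' containing `im_center`, or the strongest trace when that bin is empty.
#' The feature's mobility extent spans the merged bin range, its apex
#' mobility is the apex-intensity-weighted mean of member bin centers, and
#' its volume is the sum of raw member intensities within the seed trace's
#' RT bounds.
#'
#' @param traces Raw (unsmoothed) trace tibble (`im_bin`, `rt`,
#'   `intensity`) as from [trace_xic()]; all traces share one m/z target.
#' @param bounds Per-bin bounds tibble (`im_bin`, `apex_rt`, `rt_lo`,
#'   `rt_hi`, `apex_intensity`), e.g. from [find_bounds()] applied per bin
#'   to the smoothed traces. Bins without bounds are excluded.
#' @param im_center Target ion mobility (1/K0).
#' @param config An [index_config()] supplying the bin width.
#' @return A one-row feature tibble (`apex_rt`, `rt_lo`, `rt_hi`,
#'   `apex_intensity`, `im_lo`, `im_hi`, `apex_im`, `n_bins`, `volume`),
#'   or a zero-row tibble when there is nothing to cluster.
#' @export
cluster_im <- function(traces, bounds, im_center, config = index_config()) {
  empty <- tibble(apex_rt = double(), rt_lo = double(), rt_hi = double(),
                  apex_intensity = double(), im_lo = double(),
                  im_hi = double(), apex_im = double(), n_bins = integer(),
                  volume = double())
  if (!nrow(bounds)) return(empty)
  tr_list <- lapply(split(traces, traces$im_bin), function(d) {
    list(bin = d$im_bin[1], i0 = NA_integer_, rt = d$rt, raw = d$intensity)
  })
  bins <- vapply(tr_list, `[[`, integer(1), "bin")
  bd_list <- lapply(seq_along(tr_list), function(i) {
    row <- bounds[bounds$im_bin == bins[i], , drop = FALSE]
    if (!nrow(row)) return(NULL)
    rt <- tr_list[[i]]$rt
    list(apex = which.min(abs(rt - row$apex_rt[1])),
         lo = which.min(abs(rt - row$rt_lo[1])),
         hi = which.min(abs(rt - row$rt_hi[1])),
         apex_int = row$apex_intensity[1])
  })
  f <- cluster_raw(tr_list, bd_list, im_center, config$im_bin_width)
  if (is.null(f)) return(empty)
  tibble(apex_rt = f$apex_rt, rt_lo = f$rt_lo, rt_hi = f$rt_hi,
         apex_intensity = f$apex_intensity, im_lo = f$im_lo,
         im_hi = f$im_hi, apex_im = f$apex_im, n_bins = f$n_bins,
         volume = f$volume)
}

#' Integrate the volume of a feature's member points
#'
#' The feature volume is the plain sum of raw (unsmoothed) member
#' intensities within the retention-time bounds; smoothing is used only
#' for apex and boundary detection.
#'
#' @param traces Raw trace tibble (`rt`, `intensity`, optionally
#'   `im_bin`).
#' @param rt_lo,rt_hi Closed retention-time bounds (minutes); defaults
#'   integrate everything.
#' @return A single non-negative number.
#' @export
feature_volume <- function(traces, rt_lo = -Inf, rt_hi = Inf) {
  if (!nrow(traces)) return(0)
  sum(traces$intensity[traces$rt >= rt_lo & traces$rt <= rt_hi])
}

#' Extract up to three isotope features for one peptide ion
#'
#' Runs the full trace / smooth / bounds / cluster / volume chain at the
#' isotope m/z targets `theoretical_mz + k * 1.003355 / charge` for
#' k = 0, 1, 2. The +1/+2 features must have their apex within one scan
#' cycle of the monoisotopic apex; isotopes without a coherent feature are
#' omitted (ordinals are preserved in the `isotope` column). No
#' monoisotopic feature means no features at all.
#'
#' @param index A `peak_index`.
#' @param mz Theoretical monoisotopic m/z of the ion (Th).
#' @param charge Charge state (>= 1).
#' @param im Precursor ion mobility (1/K0).
#' @param rt_seed Precursor retention time (minutes).
#' @param config A [trace_config()].
#' @return A tibble with one row per recovered isotope feature: `isotope`
#'   (0, 1, 2), `mz_center`, `apex_rt`, `rt_lo`, `rt_hi`,
#'   `apex_intensity`, `im_lo`, `im_hi`, `apex_im`, `n_bins`, `volume`.
#'   Zero rows is a legal outcome.
#' @export
extract_isotopes <- function(index, mz, charge, im, rt_seed,
                             config = trace_config()) {
  stopifnot(charge >= 1)
  empty <- tibble(isotope = integer(), mz_center = double(),
                  apex_rt = double(), rt_lo = double(), rt_hi = double(),
                  apex_intensity = double(), im_lo = double(),
                  im_hi = double(), apex_im = double(),
                  n_bins = integer(), volume = double())
  rows <- list()
  mono_idx <- NA_integer_
  for (k in 0:2) {
    mz_k <- mz + k * config$isotope_spacing / charge
    f <- extract_feature_raw(index, mz_k, im, rt_seed, config)
    if (is.null(f)) {
      if (k == 0) return(empty)
      next
    }
    if (k == 0) {
      mono_idx <- f$apex_rt_idx
    } else if (abs(f$apex_rt_idx - mono_idx) > 1L) {
      next  # incoherent apex: likely a different co-eluting ion
    }
    rows[[length(rows) + 1L]] <- tibble(
      isotope = k, mz_center = mz_k, apex_rt = f$apex_rt,
      rt_lo = f$rt_lo, rt_hi = f$rt_hi, apex_intensity = f$apex_intensity,
      im_lo = f$im_lo, im_hi = f$im_hi, apex_im = f$apex_im,
      n_bins = f$n_bins, volume = f$volume)
  }
  bind_rows(rows)
}
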