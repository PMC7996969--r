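#' Ion-mobility bin ordinal of a 1/K0 value
#'
#' The mobility dimension is digitized into half-open bins
#' `[k * width, (k + 1) * width)`: a value lying exactly on a bin boundary
#' belongs to the upper bin, so assignment is deterministic.
#'
#' @param im Inverse reduced ion mobility value(s) (1/K0), all positive.
#' @param bin_width Bin width (1/K0), positive.
#' @return Integer bin ordinal(s), `floor(im / bin_width)`.
#' @export
#' @examples
#' im_bin_of(1.0, 0.002)    # 500
#' im_bin_of(0.002, 0.002)  # 1: a boundary value goes to the upper bin
im_bin_of <- function(im, bin_width = 0.002) {
  if (!length(bin_width) == 1 || !(bin_width > 0)) {
    abort("bin_width must be a single positive number",
          class = "lfq4d_domain_error")
  }
  if (any(!(im > 0))) {
    abort("ion mobility values must be positive",
          class = "lfq4d_domain_error")
  }
  as.integer(floor(im / bin_width))
}

#' Build the 4-D peak index of a run
#'
#' Assigns every peak to an ion-mobility bin ([im_bin_of()]), sorts each
#' bin by m/z (stable, so equal m/z keep input order), and attaches each
#' peak's ordinal on the run's retention-time grid. Queries then touch only
#' the bins overlapping the mobility window and binary-search the sorted
#' m/z within each.
#'
#' @param peaks Peak tibble (`rt`, `mz`, `im`, `intensity`).
#' @param config An [index_config()].
#' @param run_id Run label; defaults to the label carried by `peaks`.
#' @return An object of class `peak_index`.
#' @export
build_peak_index <- function(peaks, config = index_config(), run_id = NULL) {
  validate_peaks(peaks)
  stopifnot(inherits(config, "index_config"))
  if (is.null(run_id)) run_id <- run_id(peaks)
  grid <- rt_grid(peaks)
  n <- nrow(peaks)
  if (n == 0) {
    return(structure(
      list(run_id = run_id, config = config, rt_grid = grid,
           bin_offset = 0L, bins = list(), n_peaks = 0L,
           total_intensity = 0),
      class = "peak_index"))
  }
  bin <- im_bin_of(peaks$im, config$im_bin_width)
  rt_idx <- match(peaks$rt, grid)
  ord <- order(bin, peaks$mz, method = "radix")  # stable
  bin_s <- bin[ord]
  offset <- min(bin_s)
  slot <- bin_s - offset + 1L
  # bins: list indexed by (bin - offset + 1), NULL where empty
  bins <- vector("list", max(slot))
  splits <- split(ord, slot)
  for (k in names(splits)) {
    rows <- splits[[k]]
    bins[[as.integer(k)]] <- list(
      mz = peaks$mz[rows], rt = peaks$rt[rows], im = peaks$im[rows],
      intensity = peaks$intensity[rows], rt_idx = rt_idx[rows]
    )
  }
  structure(
    list(run_id = run_id, config = config, rt_grid = grid,
         bin_offset = offset, bins = bins, n_peaks = n,
         total_intensity = sum(peaks$intensity)),
    class = "peak_index")
}

#' @export
print.peak_index <- function(x, ...) {
  cat("<peak_index> run ", x$run_id, ": ", x$n_peaks, " peaks, ",
      sum(!vapply(x$bins, is.null, logical(1))), " occupied IM bins, ",
      length(x$rt_grid), " scan cycles\n", sep = "")
  invisible(x)
}

#' Query the 4-D index for peaks in a tolerance window
#'
#' Returns exactly the peaks with relative m/z deviation within
#' `mz_tol_ppm` of `mz_center`, absolute mobility deviation within
#' `im_tol` of `im_center`, and retention time in the closed interval
#' `[rt_lo, rt_hi]`. Only ion-mobility bins overlapping
#' `[im_center - im_tol, im_center + im_tol]` are consulted; the exact
#' mobility window is applied after bin preselection.
#'
#' @param index A `peak_index` from [build_peak_index()].
#' @param mz_center Query m/z (Th).
#' @param im_center Query ion mobility (1/K0).
#' @param rt_lo,rt_hi Closed retention-time interval (minutes).
#' @return A tibble of matching peaks (`rt`, `mz`, `im`, `intensity`,
#'   `im_bin`, `rt_idx`), ordered by IM bin then m/z.
#' @export
query_index <- function(index, mz_center, im_center, rt_lo, rt_hi) {
  stopifnot(inherits(index, "peak_index"))
  if (rt_lo > rt_hi) {
    abort("rt_lo must not exceed rt_hi", class = "lfq4d_argument_error")
  }
  hits <- query_index_raw(index, mz_center, im_center, rt_lo, rt_hi)
  tibble(rt = hits$rt, mz = hits$mz, im = hits$im,
         intensity = hits$intensity, im_bin = hits$im_bin,
         rt_idx = hits$rt_idx)
}

# binary searches over a sorted vector (no per-call sortedness scan):
# first index with v[i] >= x / first index with v[i] > x
bsearch_ge <- function(v, x) {
  lo <- 1L
  hi <- length(v) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (v[mid] < x) lo <- mid + 1L else hi <- mid
  }
  lo
}

bsearch_gt <- function(v, x) {
  lo <- 1L
  hi <- length(v) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (v[mid] <= x) lo <- mid + 1L else hi <- mid
  }
  lo
}

# Hot path: plain-vector query used by tracing. Returns list of vectors.
query_index_raw <- function(index, mz_center, im_center, rt_lo, rt_hi) {
  cfg <- index$config
  empty <- list(rt = double(), mz = double(), im = double(),
                intensity = double(), im_bin = integer(),
                rt_idx = integer())
  if (!length(index$bins)) return(empty)
  mz_lo <- mz_center * (1 - cfg$mz_tol_ppm * 1e-6)
  mz_hi <- mz_center * (1 + cfg$mz_tol_ppm * 1e-6)
  b_lo <- as.integer(floor((im_center - cfg$im_tol) / cfg$im_bin_width))
  b_hi <- as.integer(floor((im_center + cfg$im_tol) / cfg$im_bin_width))
  s_lo <- max(b_lo - index$bin_offset + 1L, 1L)
  s_hi <- min(b_hi - index$bin_offset + 1L, length(index$bins))
  if (s_lo > s_hi) return(empty)
  acc <- vector("list", s_hi - s_lo + 1L)
  j <- 0L
  for (s in s_lo:s_hi) {
    b <- index$bins[[s]]
    if (is.null(b)) next
    lo <- bsearch_ge(b$mz, mz_lo)
    hi <- bsearch_gt(b$mz, mz_hi) - 1L
    if (lo > hi) next
    sel <- lo:hi
    keep <- abs(b$im[sel] - im_center) <= cfg$im_tol &
      b$rt[sel] >= rt_lo & b$rt[sel] <= rt_hi
    if (!any(keep)) next
    sel <- sel[keep]
    j <- j + 1L
    acc[[j]] <- list(rt = b$rt[sel], mz = b$mz[sel], im = b$im[sel],
                     intensity = b$intensity[sel],
                     im_bin = rep.int(s + index$bin_offset - 1L,
                                      length(sel)),
                     rt_idx = b$rt_idx[sel])
  }
  if (j == 0L) return(empty)
  acc <- acc[seq_len(j)]
  list(
    rt = unlist(lapply(acc, `[[`, "rt"), use.names = FALSE),
    mz = unlist(lapply(acc, `[[`, "mz"), use.names = FALSE),
    im = unlist(lapply(acc, `[[`, "im"), use.names = FALSE),
    intensity = unlist(lapply(acc, `[[`, "intensity"), use.names = FALSE),
    im_bin = unlist(lapply(acc, `[[`, "im_bin"), use.names = FALSE),
    rt_idx = unlist(lapply(acc, `[[`, "rt_idx"), use.names = FALSE)
  )
}
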