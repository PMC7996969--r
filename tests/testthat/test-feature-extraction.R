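test_that("Gaussian smoothing preserves constants, mass, and symmetry", {
  cycles <- seq(10, 12, by = 0.1)
  const <- tibble::tibble(rt = cycles, intensity = 7)
  sm <- gaussian_smooth(const, sigma_cycles = 1)
  expect_equal(sm$intensity, rep(7, length(cycles)), tolerance = 1e-12)

  impulse <- tibble::tibble(rt = cycles, intensity = 0)
  impulse$intensity[11] <- 100
  smi <- gaussian_smooth(impulse, sigma_cycles = 1)
  expect_lt(max(smi$intensity), 100)
  expect_equal(sum(smi$intensity), 100, tolerance = 1e-9)
  expect_equal(smi$intensity, rev(smi$intensity), tolerance = 1e-12)
  expect_equal(which.max(smi$intensity), 11)

  expect_error(gaussian_smooth(const[0, ], 1),
               class = "lfq4d_argument_error")
})

test_that("smoothing equals the naive convolution oracle on random traces", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:50, 1)
    sigma <- runif(1, 0.5, 2.5)
    x <- rexp(n) * 1000
    got <- lfq4d:::smooth_vec(x, sigma)
    want <- naive_gaussian_smooth(x, sigma)
    # identical kernels and zero padding: agreement to numerical precision
    expect_equal(got, want, tolerance = 1e-9)
  }
  # interior-supported mass conservation (signal clear of the edge zone
  # where the kernel is renormalized: two half-widths from the ends)
  set.seed(99)
  x <- c(numeric(15), rexp(10) * 500, numeric(15))
  expect_equal(sum(lfq4d:::smooth_vec(x, 1.5)), sum(x), tolerance = 1e-9)
})

test_that("apex and boundaries follow the threshold and valley rules", {
  rt <- seq(10.0, 10.6, by = 0.1)
  trace <- tibble::tibble(rt = rt,
                          intensity = c(0, 10, 40, 100, 40, 10, 0))
  b <- find_bounds(trace, rt_seed = 10.3)
  expect_equal(b$apex_rt, 10.3)
  expect_equal(b$rt_lo, 10.1)   # 10 >= 1% of 100, 0 < 1%
  expect_equal(b$rt_hi, 10.5)
  expect_equal(b$apex_intensity, 100)

  # two peaks with a zero valley: right bound stays left of the neighbour
  rt2 <- seq(10.0, 11.7, by = 0.1)
  int2 <- c(5, 40, 100, 40, 5, 0, 0, 0, 0, 0, 0, 0, 0, 10, 60, 80, 30, 5)
  two <- tibble::tibble(rt = rt2, intensity = int2)
  b2 <- find_bounds(two, rt_seed = 10.25)
  expect_equal(b2$apex_rt, 10.2)
  expect_lt(b2$rt_hi, 11.0)

  # all-zero trace: a no-feature result, not an error
  zero <- tibble::tibble(rt = rt, intensity = numeric(7))
  expect_equal(nrow(find_bounds(zero, 10.3)), 0)
})

test_that("bounds equal the exhaustive-scan oracle on random bimodal traces", {
  tcfg <- trace_config()
  for (s in 1:200) {
    set.seed(3000 + s)
    n <- sample(15:60, 1)
    rt <- seq(10, by = 0.1, length.out = n)
    a1 <- runif(1, 50, 1000)
    a2 <- runif(1, 50, 1000)
    c1 <- sample(n, 1)
    c2 <- sample(n, 1)
    sm <- a1 * exp(-0.5 * ((seq_len(n) - c1) / runif(1, 1, 4))^2) +
      a2 * exp(-0.5 * ((seq_len(n) - c2) / runif(1, 1, 4))^2)
    seed_rt <- rt[sample(n, 1)]
    got <- lfq4d:::find_bounds_raw(rt, sm, seed_rt, 0.4,
                                   tcfg$boundary_fraction)
    want <- bounds_oracle(rt, sm, seed_rt, 0.4, tcfg$boundary_fraction)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$apex, want$apex)
      expect_equal(got$lo, want$lo)
      expect_equal(got$hi, want$hi)
    }
  }
})

test_that("RT tracing matches region growth on the raw peak list", {
  # an ion whose apex sits 0.3 min after the seed, tails out to +/- 0.6
  cycles <- seq(0, 40, by = 0.1)
  apex_rt <- 20.3
  sigma <- 0.2
  keep <- abs(cycles - apex_rt) <= 0.6
  pk <- tibble::tibble(
    rt = cycles[keep], mz = 600,
    im = 0.9005,
    intensity = 1e4 * exp(-0.5 * ((cycles[keep] - apex_rt) / sigma)^2))
  idx <- build_peak_index(pk, index_config(), run_id = "r")
  tr <- trace_xic(idx, 600, 0.9, rt_seed = 20.0)
  expect_equal(nrow(dplyr::distinct(tr, im_bin)), 1)
  # oracle: seed window [19.6, 20.4] extended while peaks continue
  grid <- rt_grid(pk)
  occ <- match(pk$rt, grid)
  w <- range(which(grid >= 20.0 - 0.4 & grid <= 20.0 + 0.4))
  want <- region_grow_oracle(occ, length(grid), w[1], w[2],
                             trace_config()$max_gap_cycles)
  expect_equal(range(tr$rt), c(grid[want[1]], grid[want[2]]))
  # trace reproduces the raw intensities on occupied cycles
  on_grid <- tr$intensity[match(pk$rt, tr$rt)]
  expect_equal(on_grid, pk$intensity)

  # empty window yields no traces
  expect_equal(nrow(trace_xic(idx, 900, 0.9, 20)), 0)

  # an isolated clean 7-cycle peak is reproduced exactly
  pk2 <- tibble::tibble(rt = seq(5.0, 5.6, by = 0.1), mz = 500,
                        im = 1.1003,
                        intensity = c(10, 50, 200, 400, 180, 60, 12))
  idx2 <- build_peak_index(pk2, index_config(), run_id = "r2")
  tr2 <- trace_xic(idx2, 500, 1.1, rt_seed = 5.3)
  expect_equal(tr2$intensity, pk2$intensity)
})

test_that("gap rule stops extension across long empty stretches", {
  # two signal islands separated by more than max_gap empty cycles
  rt_a <- seq(10.0, 10.4, by = 0.1)
  rt_b <- seq(11.0, 11.4, by = 0.1)
  filler <- setdiff(seq(9.5, 12, by = 0.1), c(rt_a, rt_b))
  pk <- dplyr::bind_rows(
    tibble::tibble(rt = rt_a, mz = 500, im = 0.9005, intensity = 100),
    tibble::tibble(rt = rt_b, mz = 500, im = 0.9005, intensity = 80),
    tibble::tibble(rt = filler, mz = 300, im = 1.3, intensity = 1))
  idx <- build_peak_index(pk, index_config(rt_tol_min = 0.2),
                          run_id = "r")
  tr <- trace_xic(idx, 500, 0.9, rt_seed = 10.2)
  expect_true(all(tr$rt <= 10.7))  # second island unreachable (gap > 2)
})

test_that("mobility clustering groups adjacent bins like the component oracle", {
  # adjacency example: bins 449-451 merge around the seed
  mk_trace <- function(bin, rts, ints) {
    tibble::tibble(im_bin = bin, rt = rts, intensity = ints)
  }
  rts <- seq(10.0, 10.6, by = 0.1)
  ints <- c(0, 10, 40, 100, 40, 10, 0)
  traces <- dplyr::bind_rows(
    mk_trace(449L, rts, ints * 0.4), mk_trace(450L, rts, ints),
    mk_trace(451L, rts, ints * 0.5))
  bounds <- dplyr::bind_rows(lapply(c(449L, 450L, 451L), function(b) {
    tr <- traces[traces$im_bin == b, ]
    cbind(im_bin = b, find_bounds(gaussian_smooth(tr[, -1]), 10.3))
  }))
  f <- cluster_im(traces, bounds, im_center = 0.901)
  expect_equal(nrow(f), 1)
  expect_equal(f$im_lo, 449 * 0.002)
  expect_equal(f$im_hi, 452 * 0.002)
  expect_equal(f$volume, sum(traces$intensity))
  expect_gte(f$apex_im, 449.5 * 0.002)
  expect_lte(f$apex_im, 451.5 * 0.002)

  # distant bin (gap 20): only the seed-side group is retained
  far <- dplyr::bind_rows(
    mk_trace(440L, rts, ints), mk_trace(460L, rts, ints * 2))
  far_bounds <- dplyr::bind_rows(lapply(c(440L, 460L), function(b) {
    tr <- far[far$im_bin == b, ]
    cbind(im_bin = b, find_bounds(gaussian_smooth(tr[, -1]), 10.3))
  }))
  f2 <- cluster_im(far, far_bounds, im_center = 0.881)  # bin 440
  expect_equal(f2$im_lo, 440 * 0.002)
  expect_equal(f2$im_hi, 441 * 0.002)
  expect_equal(f2$volume, sum(ints))
})

test_that("bin grouping equals connected components on the adjacency graph", {
  skip_if_not_installed("igraph")
  for (s in 1:50) {
    set.seed(4000 + s)
    bins <- sort(sample(400:460, sample(3:15, 1)))
    comp <- lfq4d:::bin_components(bins, gap = 1L)
    g <- igraph::make_empty_graph(n = length(bins), directed = FALSE)
    pairs <- which(outer(bins, bins, function(a, b) {
      abs(a - b) <= 2 & a < b
    }), arr.ind = TRUE)
    if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs[, 2:1]))
    want <- igraph::components(g)$membership
    # same partition (labels may differ)
    expect_equal(length(unique(comp)), length(unique(want)))
    expect_true(all(tapply(want, comp, function(v) {
      length(unique(v)) == 1
    })))
  }
})

test_that("feature volume is the plain sum inside the bounds", {
  tr <- tibble::tibble(rt = c(1, 2, 3), intensity = c(50, 100, 50))
  expect_equal(feature_volume(tr), 200)
  expect_equal(feature_volume(tr[0, ]), 0)
  expect_equal(feature_volume(tr, rt_lo = 2, rt_hi = 3), 150)
})

test_that("isotope m/z targets follow the 13C spacing over charge", {
  pk <- demo_isotope_peaks()
  idx <- build_peak_index(pk, index_config(), run_id = "demo")
  f <- extract_isotopes(idx, mz = 500.0, charge = 2, im = 0.9,
                        rt_seed = 10.3)
  expect_equal(f$isotope, c(0L, 1L, 2L))
  expect_equal(f$mz_center, c(500.0, 500.5016775, 501.003355),
               tolerance = 1e-9)
  expect_equal(f$volume, c(100, 50, 20))
  expect_equal(f$apex_rt, rep(10.2, 3))

  # z = 1 arithmetic
  expect_equal(800 + (0:2) * 1.003355, c(800, 801.003355, 802.00671))
})

test_that("synthetic isotope envelopes are recovered with their ratios", {
  sim <- make_design(three_organism = FALSE, n_proteins = 10, seed = 17)
  cfg <- sim_config(seed = 17, noise_cv = 0, n_decoy_peaks = 0,
                    noise_floor = 0)
  r <- simulate_run(sim, "A", 1, cfg)
  idx <- build_peak_index(r$peaks)
  cat_ <- sim$catalog
  for (i in seq_len(nrow(cat_))) {
    f <- extract_isotopes(idx, cat_$theoretical_mz[i], cat_$charge[i],
                          cat_$apex_im[i], cat_$apex_rt[i])
    expect_gte(nrow(f), 2)
    truth <- r$truth[r$truth$ion ==
                       ion_key(cat_$peptide[i], cat_$charge[i]), ]
    vols <- c(truth$true_volume_iso0, truth$true_volume_iso1,
              truth$true_volume_iso2)
    got <- vols * 0
    got[f$isotope + 1] <- f$volume
    ratio_err <- abs(got / got[1] - vols / vols[1])
    expect_lt(max(ratio_err, na.rm = TRUE), 0.1)
  }
})

test_that("volume does not depend on input peak order", {
  pk <- demo_isotope_peaks()
  set.seed(1)
  shuffled <- pk[sample(nrow(pk)), ]
  attr(shuffled, "run_id") <- "demo"
  i1 <- build_peak_index(pk, run_id = "demo")
  i2 <- build_peak_index(shuffled, run_id = "demo")
  f1 <- extract_isotopes(i1, 500, 2, 0.9, 10.3)
  f2 <- extract_isotopes(i2, 500, 2, 0.9, 10.3)
  expect_equal(f1$volume, f2$volume)
})

test_that("tightening the boundary fraction never increases volume", {
  sim <- make_design(three_organism = FALSE, n_proteins = 5, seed = 23)
  cfg <- sim_config(seed = 23, noise_cv = 0, n_decoy_peaks = 0)
  r <- simulate_run(sim, "A", 1, cfg)
  idx <- build_peak_index(r$peaks)
  cat_ <- sim$catalog
  fracs <- c(0.005, 0.01, 0.05, 0.2, 0.5)
  for (i in seq_len(nrow(cat_))) {
    vols <- vapply(fracs, function(fr) {
      f <- extract_isotopes(idx, cat_$theoretical_mz[i], cat_$charge[i],
                            cat_$apex_im[i], cat_$apex_rt[i],
                            config = trace_config(boundary_fraction = fr))
      sum(f$volume)
    }, numeric(1))
    expect_true(all(diff(vols) <= 1e-9))
  }
})
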