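mkgrid <- function(v) grid_create(matrix(v, 1), c(0, 1), 1)

test_that("NDVI arithmetic, bounds and nodata behave as specified", {
  nir <- mkgrid(c(0.4, 0.8, 0.0, 0.0))
  red <- mkgrid(c(0.4, 0.2, 0.2, 0.0))
  ndvi <- compute_ndvi(nir, red)
  expect_equal(as.vector(ndvi$values)[1:3], c(0, 0.6, -1))
  expect_true(is.na(ndvi$values[1, 4]))       # zero denominator -> nodata
  expect_error(compute_ndvi(nir, grid_create(matrix(0.1, 2, 2), c(0, 2), 1)),
               "co-registered")
})

test_that("ExG arithmetic on chromatic coordinates, black pixels -> 0", {
  r <- mkgrid(c(0.2, 0.0, 0.50, 0))
  g <- mkgrid(c(0.2, 1.0, 0.25, 0))
  b <- mkgrid(c(0.2, 0.0, 0.25, 0))
  expect_message(exg <- compute_exg(r, g, b), "1 black pixels")
  expect_equal(as.vector(exg$values), c(0, 2, -0.25, 0))
})

test_that("pixel classification applies shade precedence and the NDVI cut", {
  ndvi <- mkgrid(c(0.9, 0.26, 0.27, 0.5))
  exg <- mkgrid(c(-0.10, 0.1, 0.1, 0.1))
  cm <- classify_pixels(ndvi, exg)
  # shaded beats a high NDVI; 0.26 defoliated; 0.27 already non-defoliated
  expect_equal(as.vector(cm$values), c(3L, 1L, 2L, 2L))
})

test_that("every in-mask pixel gets exactly one of the three labels", {
  run <- get_small_run()
  cm <- run$classmap$values
  ok <- !is.na(run$ndvi$values)
  expect_true(all(cm[ok] %in% 1:3))
  expect_true(all(cm[!ok] == 0L))
})

test_that("raising the defoliation threshold never shrinks the defoliated set", {
  run <- get_small_run()
  thr_seq <- seq(0.1, 0.5, by = 0.1)
  counts <- vapply(thr_seq, function(t) {
    cm <- classify_pixels(run$ndvi, run$exg, thresholds(ndvi_defoliation = t))
    sum(cm$values == 1L)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("index bounds hold on generated scenes", {
  run <- get_small_run()
  v <- run$ndvi$values[!is.na(run$ndvi$values)]
  expect_true(all(v >= -1 & v <= 1))
  e <- run$exg$values[!is.na(run$exg$values)]
  expect_true(all(e >= -1 - 1e-9 & e <= 2 + 1e-9))
})

test_that("threshold scans find the gap, break ties low, and flatline on one class", {
  # perfectly separated classes: any threshold in the gap is optimal,
  # the lowest candidate is returned
  values <- c(rep(0.1, 5), rep(0.6, 5))
  labels <- c(rep("pine", 5), rep("oak", 5))
  out <- scan_threshold(values, labels, 0, 1, step = 0.01, hi_label = "oak")
  expect_equal(out$best, 0.11)
  expect_equal(max(out$curve$accuracy), 1)
  # single class: constant accuracy curve
  out1 <- scan_threshold(rep(0.3, 8), rep("oak", 8), 0.2, 0.4,
                         hi_label = "oak")
  expect_equal(length(unique(round(out1$curve$accuracy[
    out1$curve$threshold <= 0.3], 10))), 1L)
})

test_that("the scan recovers the Bayes boundary of the pixel mixtures", {
  # defoliated vs healthy pine pixel NDVI; boundary where the densities
  # cross between the means (equal priors)
  f <- function(t) dnorm(t, 0.12, 0.05) - dnorm(t, 0.35, 0.04)
  bayes <- uniroot(f, c(0.15, 0.32))$root
  set.seed(21)
  n <- 4000
  values <- c(rnorm(n, 0.12, 0.05), rnorm(n, 0.35, 0.04))
  labels <- rep(c("defoliated", "healthy"), each = n)
  out <- scan_threshold(values, labels, 0, 0.6, step = 0.01,
                        hi_label = "healthy")
  expect_lte(abs(out$best - bayes), 0.05)
})

test_that("unsupervised clustering isolates the shadow ExG mode", {
  run <- get_small_run()
  crowns <- run$delin$label
  mask <- crown_mask <- grid_value_at(
    crowns,
    grid_cell_center(run$exg, rep(seq_len(nrow(run$exg$values)),
                                  times = ncol(run$exg$values)),
                     rep(seq_len(ncol(run$exg$values)),
                         each = nrow(run$exg$values)))[, 1],
    grid_cell_center(run$exg, rep(seq_len(nrow(run$exg$values)),
                                  times = ncol(run$exg$values)),
                     rep(seq_len(ncol(run$exg$values)),
                         each = nrow(run$exg$values)))[, 2]) > 0
  mask <- matrix(mask, nrow(run$exg$values), ncol(run$exg$values))
  thr <- unsupervised_shade_threshold(run$exg, mask)
  sh <- run$scene$ms$shadow$values == 1 & mask
  lit <- run$scene$ms$shadow$values == 0 & mask
  expect_gt(thr, mean(run$exg$values[sh]))
  expect_lt(thr, mean(run$exg$values[lit]))
  expect_gte(mean(run$exg$values[sh] < thr), 0.9)
})
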