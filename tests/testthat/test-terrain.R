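test_that("a perfectly flat cloud is classified entirely as ground", {
  set.seed(1)
  pts <- expand.grid(x = seq(0, 30, by = 1), y = seq(0, 30, by = 1))
  cloud <- data.table::data.table(x = pts$x, y = pts$y, z = 100)
  out <- classify_ground(cloud)
  expect_true(all(out$classification == 2L))
})

test_that("a single elevated point over flat ground is the only non-ground", {
  pts <- expand.grid(x = seq(0, 30, by = 1), y = seq(0, 30, by = 1))
  cloud <- data.table::data.table(x = c(pts$x, 15.3), y = c(pts$y, 14.7),
                                  z = c(rep(50, nrow(pts)), 55))
  out <- classify_ground(cloud)
  expect_equal(which(out$classification != 2L), nrow(pts) + 1L)
})

test_that("points far below the surface are flagged as low noise", {
  pts <- expand.grid(x = seq(0, 30, by = 1), y = seq(0, 30, by = 1))
  cloud <- data.table::data.table(x = c(pts$x, 10.5), y = c(pts$y, 10.5),
                                  z = c(rep(50, nrow(pts)), 46))
  out <- classify_ground(cloud)
  expect_equal(out$classification[nrow(pts) + 1L], 7L)
})

test_that("degenerate point sets raise geometry errors", {
  expect_error(classify_ground(data.table::data.table(
    x = c(1, 2), y = c(1, 2), z = c(0, 0))))
  expect_error(classify_ground(data.table::data.table(
    x = rep(1, 10), y = rep(2, 10), z = rnorm(10))),
    "degenerate")
})

test_that("ground classification recovers generator-labeled ground points", {
  run <- get_small_run()
  gt <- run$scene$cloud$truth_ground
  expect_gte(mean(run$cloud$classification[gt] == 2L), 0.95)
  # canopy leakage into ground stays marginal
  expect_lte(mean(run$cloud$classification[!gt] == 2L), 0.02)
})

test_that("the gridded DTM recovers the true terrain within 0.15 m RMSE", {
  run <- get_small_run()
  expect_lte(dtm_rmse(run$dtm, run$scene$dtm_true), 0.15)
})

test_that("height normalization is exact subtraction with clamping", {
  dtm <- grid_empty(0, 0, 10, 10, 1, fill = 100)
  cloud <- data.table::data.table(x = c(5, 2.5, 7.5, 15),
                                  y = c(5, 2.5, 7.5, 5),
                                  z = c(100, 112, 99.5, 130))
  out <- suppressMessages(normalize_heights(cloud, dtm))
  expect_equal(nrow(out), 3L)          # the outside point is dropped
  expect_equal(out$z, c(0, 12, 0))     # on-DTM -> 0; clamped negative -> 0
  expect_message(normalize_heights(cloud, dtm), "dropped 1 points")
})

test_that("normalized canopy heights match the generating envelope", {
  run <- get_small_run()
  sc <- run$scene
  cfg <- sc$config
  est_gz <- grid_bilinear(run$dtm, sc$cloud$x, sc$cloud$y)
  norm_z <- pmax(sc$cloud$z - est_gz, 0)
  # noise-free envelope height of each canopy point, from the truth table
  tr <- sc$truth$trees
  idx <- match(sc$cloud$truth_tree, tr$tree_id)
  keep <- which(sc$cloud$truth_tree > 0L & is.finite(norm_z))
  r <- sqrt((sc$cloud$x[keep] - tr$x[idx[keep]])^2 +
              (sc$cloud$y[keep] - tr$y[idx[keep]])^2)
  re <- tr$crown_radius[idx[keep]] * (1 - cfg$canopy_edge_loss)
  H <- tr$height[idx[keep]]
  h_true <- ifelse(tr$species[idx[keep]] == "pine",
                   H * (1 - (1 - cfg$pine_edge_fraction) * r / re),
                   H * sqrt(pmax(0, 1 - (r / re)^2)))
  err <- norm_z[keep] - h_true
  expect_gte(mean(abs(err) <= 2 * cfg$vertical_noise_sd), 0.95)
})

test_that("the CHM is a per-cell height maximum with the contract's bounds", {
  run <- get_small_run()
  chm <- run$chm
  expect_true(all(chm$values >= 0))
  norm <- suppressMessages(normalize_heights(run$cloud, run$dtm))
  rc <- grid_rowcol(chm, norm$x, norm$y)
  dt <- data.table::data.table(row = rc$row, col = rc$col, z = norm$z)
  mx <- dt[!is.na(row), list(z = max(z)), by = c("row", "col")]
  # every populated cell equals the max height of its points...
  expect_equal(chm$values[cbind(mx$row, mx$col)], mx$z)
  # ...and every cell is bounded by the max in its 3x3 neighbourhood
  filled <- matrix(NA_real_, nrow(chm$values), ncol(chm$values))
  filled[cbind(mx$row, mx$col)] <- mx$z
  for (k in sample(which(!is.na(filled)), 500)) {
    r <- (k - 1) %% nrow(filled) + 1; c <- (k - 1) %/% nrow(filled) + 1
    nb <- filled[max(1, r - 1):min(nrow(filled), r + 1),
                 max(1, c - 1):min(ncol(filled), c + 1)]
    expect_lte(chm$values[r, c], max(nb, na.rm = TRUE) + 1e-9)
  }
})

test_that("adding a higher point to a cell never lowers the CHM", {
  cloud <- data.table::data.table(
    x = runif(200, 0, 10), y = runif(200, 0, 10), z = runif(200, 0, 5))
  chm1 <- compute_chm(cloud, cell_size = 1)
  higher <- data.table::rbindlist(list(
    cloud, data.table::data.table(x = 5.2, y = 5.2, z = 50)))
  chm2 <- compute_chm(higher, cell_size = 1)
  expect_true(all(chm2$values - chm1$values >= -1e-9))
  rc <- grid_rowcol(chm2, 5.2, 5.2)
  expect_equal(chm2$values[rc$row, rc$col], 50)
})
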