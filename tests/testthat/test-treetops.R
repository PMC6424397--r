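test_that("a single cone yields exactly one apex at its top", {
  chm <- cone_chm(c(20, 20), 8, 6)
  tops <- detect_treetops(chm)
  expect_equal(nrow(tops), 1L)
  expect_lte(abs(tops$row - 20) + abs(tops$col - 20), 1)
  # reported height is the original CHM value, not the smoothed one
  expect_equal(tops$height, chm$values[tops$row, tops$col])
})

test_that("two separated cones yield two apexes", {
  chm <- cone_chm(c(12, 12), 8, 6)
  chm2 <- cone_chm(c(28, 28), 10, 6)
  chm$values <- pmax(chm$values, chm2$values)
  tops <- detect_treetops(chm)
  expect_equal(nrow(tops), 2L)
})

test_that("an all-zero CHM yields an empty treetop list", {
  chm <- grid_create(matrix(0, 20, 20), c(0, 10), 0.5)
  expect_equal(nrow(detect_treetops(chm)), 0L)
})

test_that("min_height suppresses low maxima", {
  chm <- cone_chm(c(20, 20), 1.5, 6)
  expect_equal(nrow(detect_treetops(chm, min_height = 2)), 0L)
  expect_equal(nrow(detect_treetops(chm, min_height = 0.5)), 1L)
})

test_that("plateaus delegate to the top-left representative", {
  # a fully constant CHM is one giant plateau: exactly one apex, at the
  # row-major first pixel
  flat <- grid_create(matrix(4, 12, 12), c(0, 6), 0.5)
  tops <- detect_treetops(flat, min_height = 2)
  expect_equal(nrow(tops), 1L)
  expect_equal(c(tops$row, tops$col), c(1L, 1L))
  # a broad flat top: interior cells with constant windows are never
  # reported on their own, and the result equals the brute-force oracle
  v <- matrix(0, 21, 21)
  v[5:16, 5:16] <- 5
  chm <- grid_create(v, c(0, 10.5), 0.5)
  tops2 <- detect_treetops(chm, min_height = 0.1)
  oracle <- brute_force_tops(chm, min_height = 0.1)
  expect_equal(unname(as.matrix(tops2[, c("row", "col")])), oracle)
  sm <- grid_mean_filter(chm, 3)$values
  for (k in seq_len(nrow(tops2))) {
    r <- tops2$row[k]; c <- tops2$col[k]
    win <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
    # reported cells either see a lower neighbour or are the top-left
    expect_true(any(win < sm[r, c]) || (r == 6 && c == 6))
  }
})

test_that("detection equals the brute-force window-maximum oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    nr <- sample(20:50, 1); nc <- sample(20:50, 1)
    v <- matrix(0, nr, nc)
    for (k in 1:6) {
      r0 <- sample(nr, 1); c0 <- sample(nc, 1)
      h <- runif(1, 3, 12); rad <- sample(3:7, 1)
      for (r in max(1, r0 - rad):min(nr, r0 + rad))
        for (c in max(1, c0 - rad):min(nc, c0 + rad)) {
          d <- sqrt((r - r0)^2 + (c - c0)^2)
          if (d <= rad) v[r, c] <- max(v[r, c], h * (1 - d / (rad + 1)))
        }
    }
    v <- v + matrix(runif(nr * nc, 0, 0.01), nr, nc)
    chm <- grid_create(v, c(0, nr * 0.5), 0.5)
    tops <- detect_treetops(chm)
    oracle <- brute_force_tops(chm)
    got <- unname(as.matrix(tops[, c("row", "col")]))
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE])
  }
})

test_that("an isolated cone's crown covers the above-threshold disc", {
  chm <- cone_chm(c(20, 20), 8, 10)
  tops <- detect_treetops(chm)
  delin <- delineate_crowns(chm, tops, exclusion_fraction = 0.3,
                            max_radius_m = 10)
  crown <- delin$crowns[[1]]
  keep <- which(chm$values >= 0.3 * tops$height &
                  chm$values > 0, arr.ind = TRUE)
  d <- sqrt((keep[, 1] - tops$row)^2 + (keep[, 2] - tops$col)^2) *
    chm$cell_size
  keep <- keep[d <= 10, , drop = FALSE]
  in_crown <- paste(crown$cells[, 1], crown$cells[, 2])
  expect_true(all(paste(keep[, 1], keep[, 2]) %in% in_crown))
  expect_true(paste(tops$row, tops$col) %in% in_crown)
})

test_that("two identical adjacent trees split along the perpendicular bisector", {
  chm <- cone_chm(c(20, 12), 8, 8)
  chm2 <- cone_chm(c(20, 28), 8, 8)
  chm$values <- pmax(chm$values, chm2$values)
  tops <- detect_treetops(chm)
  expect_equal(nrow(tops), 2L)
  delin <- delineate_crowns(chm, tops, max_radius_m = 10)
  for (cr in delin$crowns) {
    own_col <- tops$col[tops$tree_id == cr$tree_id]
    # bisector is the vertical line col = 20; allow the shared pixel line
    if (own_col < 20) expect_true(all(cr$cells[, 2] <= 20))
    else expect_true(all(cr$cells[, 2] >= 20))
  }
})

test_that("crowns partition the canopy pixels and contain their apexes", {
  run <- get_small_run()
  lab <- run$delin$label$values
  counts <- table(lab[lab > 0])
  total_cells <- sum(vapply(run$delin$crowns,
                            function(cr) nrow(cr$cells), numeric(1)))
  expect_equal(sum(counts), total_cells)  # no pixel in two crowns
  for (cr in run$delin$crowns) {
    expect_equal(lab[cr$apex[1], cr$apex[2]], cr$tree_id)
  }
})

test_that("an apex outside the CHM is an input error naming the id", {
  chm <- cone_chm(c(20, 20), 8, 6)
  tops <- detect_treetops(chm)
  tops$row <- 999L
  expect_error(delineate_crowns(chm, tops), "apex outside CHM.*1")
})

test_that("Sørensen overlap matches hand-computed cases and is symmetric", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(sorensen(sq, sq)$SC, 1)
  far <- sq; far[, 1] <- far[, 1] + 3
  expect_equal(sorensen(sq, far)$SC, 0)
  shifted <- sq; shifted[, 1] <- shifted[, 1] + 0.5
  ov <- sorensen(sq, shifted)
  expect_equal(ov$A, 0.5); expect_equal(ov$B, 0.5); expect_equal(ov$C, 0.5)
  expect_equal(ov$SC, 0.5)
  # symmetry on irregular convex pairs
  set.seed(2)
  for (k in 1:5) {
    p <- disc_polygon(runif(2, 0, 4), runif(1, 1, 2), n = 12)
    q <- disc_polygon(runif(2, 0, 4), runif(1, 1, 2), n = 17)
    expect_equal(sorensen(p, q)$SC, sorensen(q, p)$SC, tolerance = 1e-9)
  }
})

test_that("greedy apex matching is one-to-one within the distance cap", {
  det <- data.frame(tree_id = 1:3, x = c(0, 5, 20), y = c(0, 0, 0))
  ref <- data.frame(tree_id = 11:13, x = c(0.4, 5.2, 40), y = c(0, 0.3, 0))
  mt <- match_trees(det, ref, max_dist = 1)
  expect_equal(nrow(mt$pairs), 2L)
  expect_equal(sort(mt$pairs$reference_id), c(11, 12))
  expect_equal(mt$recall, 2 / 3)
  expect_equal(mt$precision, 2 / 3)
})

test_that("detection recall and precision reach 0.95 on well-separated stands", {
  run <- get_small_run()
  expect_gte(run$match$recall, 0.95)
  expect_gte(run$match$precision, 0.95)
})
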