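test_that("scene configuration enforces its invariants", {
  expect_error(scene_config(extent_m = c(-5, 10)), "positive")
  expect_error(scene_config(min_spacing_m = 0), "min_spacing")
  expect_error(scene_config(n_pines = 3L,
                            defoliation_fractions = c(0.5, 0.5)),
               "length")
  expect_error(scene_config(n_pines = 2L,
                            defoliation_fractions = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(scene_config(n_pines = 5L,
                            class_mix = c(non_defoliated = 1L, partial = 1L,
                                          complete = 1L)),
               "sum")
  expect_error(generate_terrain(scene_config(extent_m = c(10, 10))),
               "at least 20")
})

test_that("terrain is smooth, bounded and deterministic", {
  cfg <- scene_config(extent_m = c(100, 100), terrain_amplitude_m = 5,
                      seed = 11)
  t1 <- generate_terrain(cfg)
  expect_lte(max(t1$values) - min(t1$values), 10 + 1e-9)
  t2 <- generate_terrain(cfg)
  expect_identical(t1$values, t2$values)
  flat <- generate_terrain(scene_config(extent_m = c(40, 40),
                                        terrain_amplitude_m = 0,
                                        base_elevation_m = 250))
  expect_true(all(flat$values == 250))
})

test_that("tree packing respects spacing and fails loudly when infeasible", {
  cfg <- small_scene_config()
  dtm <- generate_terrain(cfg)
  truth <- place_trees(cfg, dtm)
  tr <- truth$trees
  dmin <- min(dist(cbind(tr$x, tr$y)))
  expect_gte(dmin, cfg$min_spacing_m)
  expect_equal(sum(tr$species == "pine"), cfg$n_pines)
  # per-class defoliation draws respect the field class definition
  pines <- tr[tr$species == "pine"]
  expect_identical(pines$true_class,
                   classify_tree(100 * pines$defoliation))
  dense <- scene_config(extent_m = c(30, 30), n_pines = 40L, n_oaks = 10L,
                        class_mix = c(non_defoliated = 40L, partial = 0L,
                                      complete = 0L),
                        min_spacing_m = 8)
  expect_error(place_trees(dense, generate_terrain(dense)),
               "packing infeasible")
})

test_that("the whole scene is deterministic under its seed", {
  cfg <- scene_config(extent_m = c(40, 40), n_pines = 3L, n_oaks = 1L,
                      class_mix = c(non_defoliated = 1L, partial = 1L,
                                    complete = 1L), seed = 99)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$ms$bands$nir$values, b$ms$bands$nir$values)
  expect_identical(a$ms$rgb$g$values, b$ms$rgb$g$values)
  expect_identical(a$truth$trees, b$truth$trees)
})

test_that("defoliated pixel mixtures are calibrated to the true fraction", {
  sc <- get_small_scene()
  cls <- sc$ms$class_map$values
  tr <- sc$truth$trees
  ms <- sc$ms$class_map
  d <- dim(cls)
  ctr <- grid_cell_center(ms, rep(seq_len(d[1]), times = d[2]),
                          rep(seq_len(d[2]), each = d[1]))
  for (i in which(tr$species == "pine")) {
    inside <- (ctr[, 1] - tr$x[i])^2 + (ctr[, 2] - tr$y[i])^2 <=
      tr$crown_radius[i]^2
    px <- as.vector(cls)[inside]
    n <- length(px)
    frac <- mean(px == 3L)  # defoliated code
    expect_lte(abs(frac - tr$defoliation[i]), 1 / n + 1e-12)
  }
})

test_that("generated class NDVI means are ordered soil < defoliated < pine < oak", {
  sc <- get_small_scene()
  ndvi <- compute_ndvi(sc$ms$bands$nir, sc$ms$bands$red)$values
  cls <- sc$ms$class_map$values
  sh <- sc$ms$shadow$values == 1
  m <- vapply(0:3, function(k) mean(ndvi[cls == k & !sh]), numeric(1))
  # codes: 0 soil, 1 oak, 2 healthy pine, 3 defoliated pine
  expect_true(m[1] < m[4] && m[4] < m[3] && m[3] < m[2])
})

test_that("healthy pine crowns have mean NDVI at the generating mean", {
  cfg <- scene_config(extent_m = c(50, 50), n_pines = 4L, n_oaks = 0L,
                      defoliation_fractions = rep(0, 4), seed = 5)
  sc <- generate_scene(cfg)
  ndvi <- compute_ndvi(sc$ms$bands$nir, sc$ms$bands$red)
  tr <- sc$truth$trees
  d <- dim(ndvi$values)
  ctr <- grid_cell_center(ndvi, rep(seq_len(d[1]), times = d[2]),
                          rep(seq_len(d[2]), each = d[1]))
  sh <- as.vector(sc$ms$shadow$values == 1)
  for (i in seq_len(nrow(tr))) {
    inside <- (ctr[, 1] - tr$x[i])^2 + (ctr[, 2] - tr$y[i])^2 <=
      tr$crown_radius[i]^2 & !sh
    v <- as.vector(ndvi$values)[inside]
    # 3 standard errors of the generating distribution (band noise adds
    # a little spread, absorbed by the observed sd)
    expect_lte(abs(mean(v) - 0.35), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("cast shadows are isolated by ExG below the shade threshold", {
  sc <- get_small_scene()
  exg <- compute_exg(sc$ms$rgb$r, sc$ms$rgb$g, sc$ms$rgb$b)
  sh <- sc$ms$shadow$values == 1
  expect_gt(sum(sh), 100)
  expect_gte(mean(exg$values[sh] < -0.06), 0.9)
})

test_that("point clouds stay above the terrain except injected outliers", {
  cfg <- scene_config(extent_m = c(40, 40), n_pines = 2L, n_oaks = 1L,
                      class_mix = c(non_defoliated = 2L, partial = 0L,
                                    complete = 0L),
                      n_low_outliers = 5L, seed = 13)
  dtm <- generate_terrain(cfg)
  truth <- place_trees(cfg, dtm)
  cloud <- render_point_cloud(truth, dtm, cfg)
  gz <- grid_bilinear(dtm, cloud$x, cloud$y)
  normal <- cloud$truth_tree >= 0L
  expect_true(all(cloud$z[normal] >= gz[normal] - 0.5))
  expect_equal(sum(cloud$truth_tree == -1L), 5L)
  expect_true(all(cloud$z[cloud$truth_tree == -1L] < gz[cloud$truth_tree == -1L] - 0.5))
})
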