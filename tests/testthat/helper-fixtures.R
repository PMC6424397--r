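# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# small 9-tree stand: fast enough for per-module tests
small_scene_config <- function(seed = 7) {
  scene_config(extent_m = c(60, 60), n_pines = 6, n_oaks = 3,
               class_mix = c(non_defoliated = 2L, partial = 2L,
                             complete = 2L),
               seed = seed)
}

get_small_scene <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <-
      generate_scene(small_scene_config())
  .fixtures$small
}

# the small scene taken through every pipeline stage, in memory
get_small_run <- function() {
  if (!is.null(.fixtures$small_run)) return(.fixtures$small_run)
  sc <- get_small_scene()
  .fixtures$small_run <- run_scene_stages(sc)
  .fixtures$small_run
}

# the full study-scale stand: 110 trees, field class mix 13/29/43 + 25 oaks
get_full_run <- function() {
  if (!is.null(.fixtures$full_run)) return(.fixtures$full_run)
  sc <- generate_scene(scene_config(seed = 42))
  .fixtures$full_run <- run_scene_stages(sc)
  .fixtures$full_run
}

run_scene_stages <- function(sc) {
  cl <- classify_ground(sc$cloud)
  dtm <- grid_dtm(cl)
  norm <- suppressMessages(normalize_heights(cl, dtm))
  chm <- compute_chm(norm)
  tops <- detect_treetops(chm)
  delin <- delineate_crowns(chm, tops)
  ndvi <- compute_ndvi(sc$ms$bands$nir, sc$ms$bands$red)
  exg <- compute_exg(sc$ms$rgb$r, sc$ms$rgb$g, sc$ms$rgb$b)
  classmap <- classify_pixels(ndvi, exg)
  records <- assess_trees(delin$label, ndvi, classmap)
  mt <- match_trees(tops, sc$truth$trees, max_dist = 1)
  list(scene = sc, cloud = cl, dtm = dtm, chm = chm, tops = tops,
       delin = delin, ndvi = ndvi, exg = exg, classmap = classmap,
       records = records, match = mt)
}

# RMSE between an estimated DTM and the true terrain, at DTM cell centers
dtm_rmse <- function(dtm, dtm_true) {
  d <- dim(dtm$values)
  ctr <- grid_cell_center(dtm, rep(seq_len(d[1]), times = d[2]),
                          rep(seq_len(d[2]), each = d[1]))
  tz <- grid_bilinear(dtm_true, ctr[, 1], ctr[, 2])
  sqrt(mean((as.vector(dtm$values) - tz)^2, na.rm = TRUE))
}

# join estimated records to reference truth through apex matching
matched_records <- function(run) {
  pairs <- run$match$pairs
  est <- run$records[match(pairs$detected_id, run$records$tree_id)]
  tr <- run$scene$truth$trees
  ref <- tr[match(pairs$reference_id, tr$tree_id)]
  list(pairs = pairs, est = est, ref = ref)
}

# printed reference confusion matrices shipped with the package
load_pixel_confusion <- function() {
  read_confusion_csv(system.file("extdata", "pixel_confusion.csv",
                                 package = "defoliatr"))
}
load_tree_confusion <- function() {
  read_confusion_csv(system.file("extdata", "tree_confusion_itde.csv",
                                 package = "defoliatr"))
}

# brute-force treetop oracle: exhaustive window scan on the smoothed CHM
brute_force_tops <- function(chm, smooth_window = 3L, search_window = 3L,
                             min_height = 2) {
  sm <- grid_mean_filter(chm, smooth_window)$values
  h <- (search_window - 1L) / 2L
  nr <- nrow(sm); nc <- ncol(sm)
  hits <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- sm[r, c]
    if (is.na(v) || v < min_height) next
    win <- sm[max(1, r - h):min(nr, r + h), max(1, c - h):min(nc, c + h)]
    win <- win[!is.na(win)]
    if (any(win > v)) next
    if (any(win < v)) {
      hits <- rbind(hits, c(r, c))
    } else {
      # plateau: keep only the row-major first cell of the connected
      # equal-valued component
      comp <- flood_equal(sm, r, c)
      first <- comp[order(comp[, 1], comp[, 2])[1], ]
      if (first[1] == r && first[2] == c) hits <- rbind(hits, c(r, c))
    }
  }
  hits
}

flood_equal <- function(sm, r0, c0) {
  nr <- nrow(sm); nc <- ncol(sm)
  val <- sm[r0, c0]
  seen <- matrix(FALSE, nr, nc); seen[r0, c0] <- TRUE
  stack <- list(c(r0, c0)); out <- list(c(r0, c0))
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r < 1 || r > nr || c < 1 || c > nc || seen[r, c]) next
      if (!is.na(sm[r, c]) && sm[r, c] == val) {
        seen[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
        out[[length(out) + 1L]] <- c(r, c)
      }
    }
  }
  do.call(rbind, out)
}

# ideal conical CHM used by detection/delineation unit tests
cone_chm <- function(apex_rc, apex_h, radius_cells, nr = 40, nc = 40,
                     cell = 0.5) {
  v <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- sqrt((r - apex_rc[1])^2 + (c - apex_rc[2])^2)
    if (d <= radius_cells) v[r, c] <- apex_h * (1 - d / (radius_cells + 1))
  }
  grid_create(v, c(0, nr * cell), cell)
}
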