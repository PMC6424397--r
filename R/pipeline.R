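# Pipeline configuration and the end-to-end driver.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters. `validate_pipeline_config()`
#' checks everything (file existence, band co-registration) before any
#' stage runs, so a misconfigured run fails fast.
#'
#' @param cloud path to the point cloud (`.las` or XYZ text).
#' @param bands named list of paths: `green`, `red`, `rededge`, `nir`.
#' @param rgb named list of paths: `r`, `g`, `b`.
#' @param reference_trees optional CSV with reference `tree_id`, `x`,
#'   `y`, `species`, `defoliation_pct`, `true_class`.
#' @param reference_crowns optional GeoJSON of reference crown polygons
#'   (feature ids matching the reference tree ids).
#' @param out_dir output directory (created if missing).
#' @param ground a [ground_params()] list.
#' @param thresholds_ a [thresholds()] list.
#' @param smooth_window,search_window,min_height treetop detection
#'   parameters ([detect_treetops()]).
#' @param exclusion_fraction,max_radius_m crown delineation parameters
#'   ([delineate_crowns()]).
#' @param dtm_cell,chm_cell grid resolutions (m).
#' @param seed RNG seed recorded in the run log (stages are
#'   deterministic; the seed feeds the unsupervised clustering).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cloud, bands, rgb,
                            reference_trees = NULL, reference_crowns = NULL,
                            out_dir = "results",
                            ground = ground_params(),
                            thresholds_ = thresholds(),
                            smooth_window = 3L, search_window = 3L,
                            min_height = 2,
                            exclusion_fraction = 0.3, max_radius_m = 6,
                            dtm_cell = 1, chm_cell = 0.5,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @return `cfg`, invisibly; errors describe the first problem found.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- c("green", "red", "rededge", "nir")
  if (!all(need %in% names(cfg$bands)))
    stop("missing multispectral band(s): ",
         paste(setdiff(need, names(cfg$bands)), collapse = ", "))
  if (!all(c("r", "g", "b") %in% names(cfg$rgb)))
    stop("missing RGB channel path(s)")
  paths <- c(cfg$cloud, unlist(cfg$bands), unlist(cfg$rgb),
             cfg$reference_trees, cfg$reference_crowns)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  grids <- lapply(c(cfg$bands[need], cfg$rgb), read_raster)
  for (g in grids[-1]) {
    if (!grids_aligned(grids[[1]], g))
      stop("band rasters are not co-registered")
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
write_pipeline_config <- function(cfg, path) {
  plain <- lapply(cfg, function(v) if (is.list(v)) unclass(v) else v)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(
    y[setdiff(names(y), c("ground", "thresholds_"))],
    list(ground = do.call(ground_params, y$ground),
         thresholds_ = do.call(thresholds, y$thresholds_))))
  cfg
}

#' Write the rendered inputs of a synthetic scene to disk
#'
#' Materialises a generated scene in the pipeline's input formats:
#' XYZ CSV point cloud, ASCII-grid band rasters, reference tree table
#' (CSV) and crown polygons (GeoJSON), plus truth rasters for
#' validation. All text formats, byte-stable under a fixed seed.
#'
#' @param scene output of [generate_scene()].
#' @param dir target directory.
#' @return a [pipeline_config()] pointing at the written files.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_point_cloud(scene$cloud[, c("x", "y", "z")], p("cloud.csv"))
  for (nm in names(scene$ms$bands))
    write_raster(scene$ms$bands[[nm]], p(paste0("band_", nm, ".asc")))
  for (nm in names(scene$ms$rgb))
    write_raster(scene$ms$rgb[[nm]], p(paste0("rgb_", nm, ".asc")))
  write_raster(scene$dtm_true, p("dtm_true.asc"))
  write_raster(scene$ms$class_map, p("truth_class_map.asc"))
  write_raster(scene$ms$shadow, p("truth_shadow.asc"))
  tr <- scene$truth$trees
  ref <- data.table::data.table(
    tree_id = tr$tree_id, x = tr$x, y = tr$y, species = tr$species,
    defoliation_pct = 100 * tr$defoliation, true_class = tr$true_class)
  data.table::fwrite(ref, p("reference_trees.csv"))
  write_geojson(scene$truth$polygons, p("reference_crowns.geojson"),
                type = "polygons")
  write_geojson(ref[, c("x", "y", "tree_id", "species")],
                p("apexes_true.geojson"), type = "points")
  pipeline_config(
    cloud = p("cloud.csv"),
    bands = list(green = p("band_green.asc"), red = p("band_red.asc"),
                 rededge = p("band_rededge.asc"), nir = p("band_nir.asc")),
    rgb = list(r = p("rgb_r.asc"), g = p("rgb_g.asc"), b = p("rgb_b.asc")),
    reference_trees = p("reference_trees.csv"),
    reference_crowns = p("reference_crowns.geojson"),
    out_dir = file.path(dir, "out"),
    seed = scene$config$seed)
}

#' Run the full assessment pipeline
#'
#' Stages, in order: ground classification, DTM, height normalization,
#' CHM, treetop detection, crown delineation, NDVI/ExG, pixel
#' classification, per-tree assessment and — when reference data are
#' configured — validation (tree matching, Sørensen overlap, confusion
#' matrix with kappa, defoliation regression). Every stage's artifact is
#' written under `out_dir`; `run_log.txt` records parameters and seed.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a results list: `tree_records`, `tops`, `crowns`,
#'   `dtm`, `chm`, `ndvi`, `exg`, `classmap`, and `validation` (NULL
#'   without reference data).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  op <- function(...) file.path(cfg$out_dir, ...)

  say("reading inputs")
  cloud <- read_point_cloud(cfg$cloud)
  bands <- lapply(cfg$bands, read_raster)
  rgb <- lapply(cfg$rgb, read_raster)

  say("classifying ground (progressive TIN densification)")
  cloud <- classify_ground(cloud, cfg$ground)
  say("gridding DTM at %g m", cfg$dtm_cell)
  dtm <- grid_dtm(cloud, cfg$dtm_cell)
  write_raster(dtm, op("dtm.asc"))
  say("normalizing heights; CHM at %g m", cfg$chm_cell)
  norm <- normalize_heights(cloud, dtm)
  chm <- compute_chm(norm, cfg$chm_cell)
  write_raster(chm, op("chm.asc"))

  say("detecting treetops")
  tops <- detect_treetops(chm, cfg$smooth_window, cfg$search_window,
                          cfg$min_height)
  say("  %d treetops; delineating crowns", nrow(tops))
  delin <- delineate_crowns(chm, tops, cfg$exclusion_fraction,
                            cfg$max_radius_m)
  write_geojson(tops[, c("x", "y", "tree_id", "height")],
                op("apexes.geojson"), type = "points")
  polys <- lapply(delin$crowns, `[[`, "polygon")
  names(polys) <- vapply(delin$crowns, function(cr)
    as.character(cr$tree_id), character(1))
  write_geojson(polys, op("crowns.geojson"), type = "polygons")

  say("computing indices and classifying pixels")
  ndvi <- compute_ndvi(bands$nir, bands$red)
  exg <- compute_exg(rgb$r, rgb$g, rgb$b)
  classmap <- classify_pixels(ndvi, exg, cfg$thresholds_)
  write_raster(ndvi, op("ndvi.asc"))
  write_raster(exg, op("exg.asc"))
  write_raster(classmap, op("classmap.asc"))

  say("assessing trees")
  records <- assess_trees(delin$label, ndvi, classmap, cfg$thresholds_)
  data.table::fwrite(records, op("tree_records.csv"))

  validation <- NULL
  if (!is.null(cfg$reference_trees)) {
    say("validating against reference data")
    validation <- validate_against_reference(
      records, tops, delin, cfg$reference_trees, cfg$reference_crowns,
      cfg$out_dir)
  }

  writeLines(c(
    "defoliatr run log",
    paste0("seed: ", cfg$seed),
    paste0("ground: ", paste(names(cfg$ground), unlist(cfg$ground),
                             sep = "=", collapse = " ")),
    paste0("thresholds: ", paste(names(cfg$thresholds_),
                                 unlist(cfg$thresholds_),
                                 sep = "=", collapse = " ")),
    paste0("detection: smooth=", cfg$smooth_window, " search=",
           cfg$search_window, " min_height=", cfg$min_height),
    paste0("delineation: exclusion=", cfg$exclusion_fraction,
           " max_radius=", cfg$max_radius_m),
    paste0("points: ", nrow(cloud), "; treetops: ", nrow(tops))),
    op("run_log.txt"))

  invisible(list(tree_records = records, tops = tops, crowns = delin,
                 dtm = dtm, chm = chm, ndvi = ndvi, exg = exg,
                 classmap = classmap, validation = validation))
}

validate_against_reference <- function(records, tops, delin, ref_trees_path,
                                       ref_crowns_path, out_dir) {
  op <- function(...) file.path(out_dir, ...)
  ref <- data.table::fread(ref_trees_path)
  mt <- match_trees(tops, ref, max_dist = 1)
  pairs <- mt$pairs

  sc <- NULL
  if (!is.null(ref_crowns_path)) {
    ref_polys <- read_geojson(ref_crowns_path)
    crown_by_id <- delin$crowns[match(pairs$detected_id,
                                      vapply(delin$crowns, `[[`, integer(1),
                                             "tree_id"))]
    sc <- data.table::rbindlist(lapply(seq_len(nrow(pairs)), function(k) {
      ov <- sorensen(crown_by_id[[k]],
                     ref_polys[[as.character(pairs$reference_id[k])]])
      data.table::data.table(detected_id = pairs$detected_id[k],
                             reference_id = pairs$reference_id[k],
                             A = ov$A, B = ov$B, C = ov$C, SC = ov$SC)
    }))
    data.table::fwrite(sc, op("sorensen.csv"))
  }

  idx <- match(pairs$detected_id, records$tree_id)
  est <- records[idx]
  ridx <- match(pairs$reference_id, ref$tree_id)
  usable <- !is.na(est$class_call)
  cm <- build_confusion(
    ref$true_class[ridx][usable], est$class_call[usable],
    class_order = c("complete", "partial", "non_defoliated", "oak"))
  write_confusion_csv(cm, op("tree_confusion.csv"))

  pine <- usable & ref$species[ridx] == "pine" &
    is.finite(est$defoliation_pct) & is.finite(ref$defoliation_pct[ridx])
  reg <- if (sum(pine) >= 2) {
    fit_regression(est$defoliation_pct[pine], ref$defoliation_pct[ridx][pine])
  } else NULL
  if (!is.null(reg))
    data.table::fwrite(data.table::data.table(
      slope = reg$a, intercept = reg$b, r_squared = reg$r_squared,
      n = reg$n), op("regression_summary.csv"))

  species_ok <- mean(est$species[usable] ==
                       ref$species[ridx][usable])
  acc <- data.table::data.table(
    metric = c("detection_recall", "detection_precision",
               "mean_sorensen", "overall_accuracy_pct", "kappa",
               "species_rate_pct", "regression_r_squared"),
    value = c(mt$recall, mt$precision,
              if (is.null(sc)) NA_real_ else mean(sc$SC),
              overall_accuracy(cm), cohens_kappa(cm),
              100 * species_ok,
              if (is.null(reg)) NA_real_ else reg$r_squared))
  data.table::fwrite(acc, op("accuracy_report.csv"))

  list(pairs = pairs, sorensen = sc, confusion = cm, regression = reg,
       accuracy = acc)
}
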