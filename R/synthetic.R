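# Synthetic mixed pine-oak scenes with known ground truth.
#
# The generator emulates the three inputs the pipeline needs -- a
# photogrammetric point cloud, co-registered multispectral + RGB rasters,
# and a reference tree table with crown polygons -- with the statistical
# structure the analysis assumes: spectrally separable classes whose NDVI
# distributions straddle the classification thresholds, per-pine
# defoliation fractions, and cast shadows that ExG isolates.

#' Scene configuration
#'
#' Builds and validates the configuration for a synthetic stand. Defaults
#' mirror the study conditions: a mixed stand of 110 trees (25 holm oaks;
#' 85 pines split 13/29/43 across the non-defoliated / partially /
#' completely defoliated field classes), 0.15 m multispectral ground
#' sample distance, 0.5 m canopy height model.
#'
#' @param extent_m width and height of the scene in metres.
#' @param ms_gsd multispectral cell size (m).
#' @param chm_gsd canopy height model cell size (m).
#' @param n_pines,n_oaks tree counts.
#' @param min_spacing_m minimum apex-to-apex distance (m).
#' @param defoliation_fractions optional per-pine defoliation fractions in
#'   `[0, 1]`; when `NULL` they are drawn from `class_mix`/`class_ranges`.
#' @param class_mix named counts of pines per field defoliation class
#'   (must sum to `n_pines`).
#' @param class_ranges per-class uniform ranges the fractions are drawn
#'   from; chosen so trees sit solidly inside their field class, the way
#'   broad visual classes are assigned in the field.
#' @param sun_azimuth_deg compass direction the sun shines from.
#' @param sun_elevation_deg sun elevation above the horizon.
#' @param point_density_per_m2 ground point density of the rendered cloud.
#' @param vertical_noise_sd vertical noise of ground points (m).
#' @param canopy_noise_sd vertical noise of canopy surface points (m).
#' @param band_noise_sd additive reflectance noise of the four MS bands.
#' @param rgb_noise_sd additive noise of the RGB channels.
#' @param terrain_amplitude_m half-range of the terrain relief (m).
#' @param base_elevation_m mean terrain elevation (m).
#' @param n_low_outliers number of injected below-ground spike points.
#' @param pine_height_range,oak_height_range apex height ranges (m).
#' @param pine_crown_ratio,oak_crown_ratio crown radius as a fraction of
#'   tree height.
#' @param pine_edge_fraction pine crown envelope height at the crown edge
#'   as a fraction of apex height (conical taper).
#' @param canopy_edge_loss fraction of the crown radius that the
#'   photogrammetric surface fails to reconstruct: the rendered point
#'   cloud covers only `(1 - canopy_edge_loss)` of each crown's radius,
#'   emulating the edge erosion of structure-from-motion canopy surfaces,
#'   while the orthomosaic shows the full crown.
#' @param defoliation_clumped logical; assign defoliated pixels as one
#'   contiguous angular sector (default) instead of at random.
#' @param shadow_within_crown logical; also shade the casting crown's own
#'   pixels (off by default: shading is modelled as a between-crown and
#'   ground nuisance).
#' @param shadow_rgb_offset_m shift (m, along the shadow direction) of the
#'   shadow pattern in the RGB channels only, to emulate the time gap
#'   between multispectral and RGB acquisitions. Default 0.
#' @param seed integer; fixes all randomness of the scene.
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(extent_m = c(160, 160),
                         ms_gsd = 0.15,
                         chm_gsd = 0.5,
                         n_pines = 85L,
                         n_oaks = 25L,
                         min_spacing_m = 8,
                         defoliation_fractions = NULL,
                         class_mix = c(non_defoliated = 13L, partial = 29L,
                                       complete = 43L),
                         class_ranges = list(non_defoliated = c(0, 0.10),
                                             partial = c(0.25, 0.75),
                                             complete = c(0.90, 1)),
                         sun_azimuth_deg = 180,
                         sun_elevation_deg = 45,
                         point_density_per_m2 = 12,
                         vertical_noise_sd = 0.05,
                         canopy_noise_sd = 0.03,
                         band_noise_sd = 0.005,
                         rgb_noise_sd = 0.01,
                         terrain_amplitude_m = 3,
                         base_elevation_m = 500,
                         n_low_outliers = 0L,
                         pine_height_range = c(5, 15),
                         oak_height_range = c(3, 8),
                         pine_crown_ratio = 0.25,
                         oak_crown_ratio = 0.45,
                         pine_edge_fraction = 0.2,
                         canopy_edge_loss = 0.1,
                         defoliation_clumped = TRUE,
                         shadow_within_crown = FALSE,
                         shadow_rgb_offset_m = 0,
                         seed = 42L) {
  cfg <- as.list(environment())
  if (length(cfg$extent_m) == 1) cfg$extent_m <- rep(cfg$extent_m, 2)
  if (any(cfg$extent_m <= 0)) stop("scene extent must be positive")
  if (cfg$min_spacing_m <= 0) stop("min_spacing_m must be > 0")
  if (cfg$ms_gsd <= 0 || cfg$chm_gsd <= 0) stop("cell sizes must be > 0")
  if (cfg$point_density_per_m2 <= 0) stop("point density must be > 0")
  if (!is.null(cfg$defoliation_fractions)) {
    f <- cfg$defoliation_fractions
    if (length(f) != cfg$n_pines)
      stop("defoliation_fractions must have length n_pines")
    if (any(f < 0 | f > 1)) stop("defoliation fractions must be in [0, 1]")
  } else if (sum(cfg$class_mix) != cfg$n_pines) {
    stop("class_mix must sum to n_pines")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "scene_config"
  cfg
}

# NDVI class distributions (mean, sd) and class colour chromas. Invented
# calibration choices: the means straddle the 0.27 defoliation and 0.42
# species thresholds with enough overlap that threshold scans are
# informative, and are ordered soil < defoliated < healthy pine < oak.
SPECTRA <- list(
  soil     = list(ndvi = c(0.10, 0.03), s = 0.45, rgb = c(0.40, 0.42, 0.38)),
  pine_def = list(ndvi = c(0.12, 0.05), s = 0.55, rgb = c(0.32, 0.33, 0.25)),
  pine_ok  = list(ndvi = c(0.35, 0.04), s = 0.55, rgb = c(0.20, 0.35, 0.18)),
  oak      = list(ndvi = c(0.50, 0.04), s = 0.55, rgb = c(0.20, 0.40, 0.20))
)
SHADOW_FACTOR <- 0.45               # multiplicative dimming of MS bands
SHADOW_RGB <- c(0.40, 0.28, 0.40) * 0.5  # dark, green-poor shadow colour
CLASS_CODES <- c(soil = 0L, oak = 1L, pine_ok = 2L, pine_def = 3L)

#' True bare-earth terrain for a scene
#'
#' A smooth surface: a gentle linear trend plus three low-frequency
#' sinusoids with random orientation and phase, rescaled so the total
#' relief (max - min) does not exceed `2 * terrain_amplitude_m`.
#' Deterministic under the scene seed.
#'
#' @param config a [scene_config()].
#' @param cell_size output cell size (m), default 1.
#' @return a `defol_grid` of elevations (the true DTM).
#' @export
generate_terrain <- function(config, cell_size = 1) {
  if (any(config$extent_m < 20))
    stop("scene extent must be at least 20 m per side")
  set.seed(config$seed + 1L)
  ex <- config$extent_m
  g <- grid_empty(0, 0, ex[1], ex[2], cell_size)
  d <- dim(g$values)
  ctr <- grid_cell_center(g, rep(seq_len(d[1]), times = d[2]),
                          rep(seq_len(d[2]), each = d[1]))
  x <- ctr[, 1]; y <- ctr[, 2]
  z <- 0.3 * (x - ex[1] / 2) / ex[1] + 0.2 * (y - ex[2] / 2) / ex[2]
  for (k in 1:3) {
    theta <- runif(1, 0, pi)
    # hill-scale undulation: absolute wavelengths, so small scenes are
    # gentle partial hillsides rather than implausibly steep bumps
    wl <- runif(1, 60, 180)
    ph <- runif(1, 0, 2 * pi)
    z <- z + runif(1, 0.5, 1) *
      sin(2 * pi * (cos(theta) * x + sin(theta) * y) / wl + ph)
  }
  if (config$terrain_amplitude_m == 0) {
    z <- rep(0, length(z))
  } else {
    z <- z - mean(z)
    m <- max(abs(z))
    if (m > 0) z <- z * config$terrain_amplitude_m / m
  }
  g$values <- matrix(z + config$base_elevation_m, d[1], d[2])
  g
}

#' Place trees and draw their ground truth
#'
#' Dart-throwing placement with a minimum apex spacing; pine and oak
#' heights are uniform in their configured ranges and crown radii are a
#' fixed fraction of height, so crown polygons are exact discs. Per-pine
#' defoliation fractions come from the config (explicit vector or
#' per-class uniform draws).
#'
#' @param config a [scene_config()].
#' @param dtm the true terrain grid (apex ground elevations are sampled
#'   from it).
#' @return a `scene_truth` list: `trees` (data.table with tree_id,
#'   species, x, y, height, crown_radius, ground_z, defoliation,
#'   true_class) and `polygons` (list of crown discs, by tree_id).
#' @export
place_trees <- function(config, dtm) {
  set.seed(config$seed + 2L)
  ex <- config$extent_m
  n <- config$n_pines + config$n_oaks
  species <- c(rep("pine", config$n_pines), rep("oak", config$n_oaks))
  height <- c(runif(config$n_pines, config$pine_height_range[1],
                    config$pine_height_range[2]),
              runif(config$n_oaks, config$oak_height_range[1],
                    config$oak_height_range[2]))
  radius <- ifelse(species == "pine", config$pine_crown_ratio,
                   config$oak_crown_ratio) * height
  xs <- numeric(n); ys <- numeric(n)
  budget <- 1000L * n
  placed <- 0L
  while (placed < n && budget > 0L) {
    m <- radius[placed + 1L] + 0.5
    if (ex[1] - 2 * m <= 0 || ex[2] - 2 * m <= 0)
      stop("packing infeasible: crown radius exceeds scene extent")
    cx <- runif(1, m, ex[1] - m); cy <- runif(1, m, ex[2] - m)
    ok <- placed == 0L ||
      min((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2) >=
      config$min_spacing_m^2
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
    budget <- budget - 1L
  }
  if (placed < n)
    stop(sprintf(paste0("packing infeasible: could not place %d trees at ",
                        "min_spacing_m = %g in a %g x %g m scene"),
                 n, config$min_spacing_m, ex[1], ex[2]))
  defol <- rep(NA_real_, n)
  if (!is.null(config$defoliation_fractions)) {
    defol[seq_len(config$n_pines)] <- config$defoliation_fractions
  } else {
    draws <- unlist(lapply(names(config$class_mix), function(cl) {
      k <- config$class_mix[[cl]]
      if (k == 0) return(numeric(0))
      rg <- config$class_ranges[[cl]]
      runif(k, rg[1], rg[2])
    }))
    defol[seq_len(config$n_pines)] <- draws
  }
  trees <- data.table::data.table(
    tree_id = seq_len(n), species = species, x = xs, y = ys,
    height = height, crown_radius = radius,
    ground_z = grid_bilinear(dtm, xs, ys),
    defoliation = defol)
  trees$true_class <- ifelse(trees$species == "oak", "oak",
                             classify_tree(100 * trees$defoliation))
  polygons <- lapply(seq_len(n), function(i)
    disc_polygon(c(xs[i], ys[i]), radius[i]))
  names(polygons) <- as.character(trees$tree_id)
  structure(list(trees = trees, polygons = polygons, config = config),
            class = "scene_truth")
}

# Crown envelope height above ground at offsets r from the apex of tree i.
# Pine: conical taper from apex height H to pine_edge_fraction * H at the
# crown edge. Oak: hemispherical cap. 0 outside the crown.
crown_envelope <- function(r, height, radius, species, config) {
  h <- numeric(length(r))
  inside <- r <= radius
  if (species == "pine") {
    f <- config$pine_edge_fraction
    h[inside] <- height * (1 - (1 - f) * r[inside] / radius)
  } else {
    h[inside] <- height * sqrt(pmax(0, 1 - (r[inside] / radius)^2))
  }
  h
}

# Canopy surface height above ground on a set of points, as the max crown
# envelope across trees (crowns are disjoint by construction, so this is
# a per-tree fill).
canopy_surface_at <- function(truth, x, y) {
  h <- numeric(length(x))
  tr <- truth$trees
  cfg <- truth$config
  for (i in seq_len(nrow(tr))) {
    near <- which(abs(x - tr$x[i]) <= tr$crown_radius[i] &
                    abs(y - tr$y[i]) <= tr$crown_radius[i])
    if (!length(near)) next
    r <- sqrt((x[near] - tr$x[i])^2 + (y[near] - tr$y[i])^2)
    h[near] <- pmax(h[near],
                    crown_envelope(r, tr$height[i], tr$crown_radius[i],
                                   tr$species[i], cfg))
  }
  h
}

#' Render a photogrammetric-style point cloud
#'
#' Ground points are sampled uniformly over the scene on the true terrain
#' with vertical noise; canopy points are sampled on the crown surface
#' envelopes (conical pines, hemispherical oaks) at twice the ground
#' density. Optional low outliers below the terrain exercise the spike
#' filter of the ground classifier.
#'
#' @param truth a `scene_truth` from [place_trees()].
#' @param dtm the true terrain grid.
#' @param config a [scene_config()].
#' @return a point-cloud `data.table` with columns `x`, `y`, `z`,
#'   `truth_ground` (generator label) and `truth_tree` (casting tree id,
#'   0 for ground).
#' @export
render_point_cloud <- function(truth, dtm, config) {
  if (config$point_density_per_m2 <= 0) stop("point density must be > 0")
  set.seed(config$seed + 3L)
  ex <- config$extent_m
  n_ground <- ceiling(ex[1] * ex[2] * config$point_density_per_m2)
  gx <- runif(n_ground, 0, ex[1]); gy <- runif(n_ground, 0, ex[2])
  gz <- grid_bilinear(dtm, gx, gy) + rnorm(n_ground, 0, config$vertical_noise_sd)
  parts <- list(data.table::data.table(
    x = gx, y = gy, z = gz, truth_ground = TRUE, truth_tree = 0L))
  tr <- truth$trees
  for (i in seq_len(nrow(tr))) {
    re <- tr$crown_radius[i] * (1 - config$canopy_edge_loss)
    np <- ceiling(pi * re^2 * 2 * config$point_density_per_m2)
    r <- re * sqrt(runif(np))
    a <- runif(np, 0, 2 * pi)
    px <- tr$x[i] + r * cos(a); py <- tr$y[i] + r * sin(a)
    hz <- crown_envelope(r, tr$height[i], re, tr$species[i], config)
    pz <- grid_bilinear(dtm, px, py) + hz +
      rnorm(np, 0, config$canopy_noise_sd)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      x = px, y = py, z = pz, truth_ground = FALSE, truth_tree = tr$tree_id[i])
  }
  if (config$n_low_outliers > 0) {
    no <- config$n_low_outliers
    ox <- runif(no, 0, ex[1]); oy <- runif(no, 0, ex[2])
    oz <- grid_bilinear(dtm, ox, oy) - runif(no, 1.5, 4)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      x = ox, y = oy, z = oz, truth_ground = FALSE, truth_tree = -1L)
  }
  cloud <- data.table::rbindlist(parts)
  cloud[stats::complete.cases(cloud[, c("x", "y", "z")])]
}

# Shadow mask on a grid: a pixel is shaded when the sun ray leaving its
# own surface point intersects some other crown's volume. The crown
# volume is the solid of revolution under the envelope; the ray is tested
# at a ladder of heights. Terrain relief is ignored for shadow geometry
# (heights are above local ground).
shadow_mask <- function(truth, template, surface_h, offset_m = 0) {
  cfg <- truth$config
  tr <- truth$trees
  d <- dim(template$values)
  shaded <- matrix(FALSE, d[1], d[2])
  own <- attr(surface_h, "tree")     # tree id owning each pixel (0 = none)
  tan_e <- tan(cfg$sun_elevation_deg * pi / 180)
  az <- cfg$sun_azimuth_deg * pi / 180
  u <- c(sin(az), cos(az))           # horizontal unit vector toward the sun
  s <- template$cell_size
  xs <- template$origin[1] + (seq_len(d[2]) - 0.5) * s
  ys <- template$origin[2] - (seq_len(d[1]) - 0.5) * s
  for (i in seq_len(nrow(tr))) {
    H <- tr$height[i]; R <- tr$crown_radius[i]
    reach <- R + H / tan_e + offset_m
    # candidate window: bounding box around the crown extended downsun
    bx <- tr$x[i] + c(-reach, reach); by <- tr$y[i] + c(-reach, reach)
    cc <- which(xs >= bx[1] & xs <= bx[2])
    rr <- which(ys >= by[1] & ys <= by[2])
    if (!length(cc) || !length(rr)) next
    px <- rep(xs[cc], each = length(rr)) - offset_m * u[1]
    py <- rep(ys[rr], times = length(cc)) - offset_m * u[2]
    idx <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
    h <- surface_h[idx]
    hit <- rep(FALSE, length(px))
    base <- if (tr$species[i] == "pine") cfg$pine_edge_fraction * H else 0
    for (zz in seq(base, H, length.out = 9L)) {
      act <- zz > h & !hit
      if (!any(act)) next
      t <- (zz - h[act]) / tan_e
      qx <- px[act] + t * u[1]; qy <- py[act] + t * u[2]
      rz <- if (tr$species[i] == "pine") {
        R * (H - zz) / ((1 - cfg$pine_edge_fraction) * H)
      } else {
        R * sqrt(max(0, 1 - (zz / H)^2))
      }
      hit[act] <- (qx - tr$x[i])^2 + (qy - tr$y[i])^2 <= rz^2
    }
    if (!cfg$shadow_within_crown) hit <- hit & own[idx] != tr$tree_id[i]
    shaded[idx] <- shaded[idx] | hit
  }
  shaded
}

#' Render the multispectral and RGB rasters of a scene
#'
#' Per-pixel reflectance is drawn from class-conditional NDVI
#' distributions (soil, defoliated pine, healthy pine, oak) and converted
#' to NIR/red pairs of fixed total brightness; green and red-edge bands
#' are plausible linear mixes. Within each pine crown, exactly
#' `round(f * n)` pixels are defoliated (`f` = the tree's true fraction),
#' assigned as a contiguous angular sector when clumping is on. Shadows
#' dim all multispectral bands multiplicatively (NDVI-preserving) and
#' recolour the RGB channels so ExG isolates them.
#'
#' @param truth a `scene_truth`.
#' @param config a [scene_config()].
#' @return list with `bands` (green/red/rededge/nir `defol_grid`s), `rgb`
#'   (r/g/b grids), `class_map` (integer truth codes: 0 soil, 1 oak,
#'   2 healthy pine, 3 defoliated pine), and `shadow` (logical truth
#'   mask as a 0/1 grid).
#' @export
render_multispectral <- function(truth, config) {
  if (config$ms_gsd <= 0) stop("ms_gsd must be > 0")
  set.seed(config$seed + 4L)
  ex <- config$extent_m
  template <- grid_empty(0, 0, ex[1], ex[2], config$ms_gsd)
  d <- dim(template$values)
  s <- template$cell_size
  xs <- template$origin[1] + (seq_len(d[2]) - 0.5) * s
  ys <- template$origin[2] - (seq_len(d[1]) - 0.5) * s

  cls <- matrix(CLASS_CODES[["soil"]], d[1], d[2])
  own <- matrix(0L, d[1], d[2])
  surf <- matrix(0, d[1], d[2])
  tr <- truth$trees
  for (i in seq_len(nrow(tr))) {
    R <- tr$crown_radius[i]
    cc <- which(abs(xs - tr$x[i]) <= R)
    rr <- which(abs(ys - tr$y[i]) <= R)
    if (!length(cc) || !length(rr)) next
    px <- rep(xs[cc], each = length(rr)); py <- rep(ys[rr], times = length(cc))
    rad <- sqrt((px - tr$x[i])^2 + (py - tr$y[i])^2)
    inside <- rad <= R
    if (!any(inside)) next
    idx <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))[inside, ,
                                                                         drop = FALSE]
    own[idx] <- tr$tree_id[i]
    surf[idx] <- crown_envelope(rad[inside], tr$height[i], R,
                                tr$species[i], config)
    if (tr$species[i] == "oak") {
      cls[idx] <- CLASS_CODES[["oak"]]
    } else {
      n_in <- nrow(idx)
      n_def <- round(tr$defoliation[i] * n_in)
      code <- rep(CLASS_CODES[["pine_ok"]], n_in)
      if (n_def > 0) {
        if (config$defoliation_clumped) {
          start <- runif(1, 0, 2 * pi)
          ang <- (atan2(py[inside] - tr$y[i], px[inside] - tr$x[i]) - start) %%
            (2 * pi)
          code[order(ang)[seq_len(n_def)]] <- CLASS_CODES[["pine_def"]]
        } else {
          code[sample.int(n_in, n_def)] <- CLASS_CODES[["pine_def"]]
        }
      }
      cls[idx] <- code
    }
  }
  attr(surf, "tree") <- own
  shaded <- shadow_mask(truth, template, surf)
  shaded_rgb <- if (config$shadow_rgb_offset_m != 0) {
    shadow_mask(truth, template, surf, offset_m = config$shadow_rgb_offset_m)
  } else shaded

  # class-conditional NDVI draw, converted to NIR/red of brightness s
  npx <- length(cls)
  ndvi <- numeric(npx); bright <- numeric(npx)
  for (nm in names(CLASS_CODES)) {
    sel <- which(cls == CLASS_CODES[[nm]])
    if (!length(sel)) next
    sp <- SPECTRA[[nm]]
    ndvi[sel] <- rnorm(length(sel), sp$ndvi[1], sp$ndvi[2])
    bright[sel] <- sp$s
  }
  ndvi <- pmin(pmax(ndvi, -0.95), 0.95)
  nir <- bright * (1 + ndvi) / 2
  red <- bright * (1 - ndvi) / 2
  green <- 0.5 * red + 0.2 * nir
  rededge <- 0.35 * red + 0.55 * nir
  dim_f <- ifelse(shaded, SHADOW_FACTOR, 1)
  mk <- function(v) {
    m <- matrix(pmax(v, 0), d[1], d[2])
    grid_create(m, template$origin, s)
  }
  bands <- list(
    green = mk(green * dim_f + rnorm(npx, 0, config$band_noise_sd)),
    red = mk(red * dim_f + rnorm(npx, 0, config$band_noise_sd)),
    rededge = mk(rededge * dim_f + rnorm(npx, 0, config$band_noise_sd)),
    nir = mk(nir * dim_f + rnorm(npx, 0, config$band_noise_sd)))

  # RGB channels from class chromas; shadow pixels get a fixed dark colour
  rgb <- list(r = numeric(npx), g = numeric(npx), b = numeric(npx))
  for (nm in names(CLASS_CODES)) {
    sel <- which(cls == CLASS_CODES[[nm]])
    if (!length(sel)) next
    ch <- SPECTRA[[nm]]$rgb
    rgb$r[sel] <- ch[1]; rgb$g[sel] <- ch[2]; rgb$b[sel] <- ch[3]
  }
  sh <- as.vector(shaded_rgb)
  rgb$r[sh] <- SHADOW_RGB[1]; rgb$g[sh] <- SHADOW_RGB[2]
  rgb$b[sh] <- SHADOW_RGB[3]
  rgb <- lapply(rgb, function(v) mk(v + rnorm(npx, 0, config$rgb_noise_sd)))

  list(bands = bands, rgb = rgb,
       class_map = grid_create(cls, template$origin, s),
       shadow = grid_create(shaded * 1, template$origin, s))
}

#' Generate a complete synthetic scene
#'
#' Runs terrain generation, tree placement, point-cloud rendering and
#' raster rendering in a fixed order, all driven by the scene seed.
#'
#' @param config a [scene_config()].
#' @return list with `config`, `dtm_true`, `truth`, `cloud`, `ms`.
#' @export
generate_scene <- function(config = scene_config()) {
  dtm <- generate_terrain(config)
  truth <- place_trees(config, dtm)
  cloud <- render_point_cloud(truth, dtm, config)
  ms <- render_multispectral(truth, config)
  list(config = config, dtm_true = dtm, truth = truth, cloud = cloud, ms = ms)
}
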