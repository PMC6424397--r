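# Per-tree species identification, defoliation scoring and classing.

# multispectral-grid pixels covered by a crown delineated on the CHM
# grid: an MS pixel belongs to the crown whose CHM cell contains its
# center. Returns linear indices into the MS grid.
crown_ms_pixels <- function(crown_label, ms_grid) {
  d <- dim(ms_grid$values)
  ctr <- grid_cell_center(ms_grid,
                          rep(seq_len(d[1]), times = d[2]),
                          rep(seq_len(d[2]), each = d[1]))
  # column-major linear index order: (r, c) -> r + (c-1)*nrow
  ids <- grid_value_at(crown_label, ctr[, 1], ctr[, 2])
  ids[is.na(ids)] <- 0L
  matrix(as.integer(ids), d[1], d[2])
}

#' Identify the species of a delineated crown
#'
#' The crown-mean NDVI (over all crown pixels with valid NDVI, shaded
#' included) decides the species: holm oak when the mean reaches the
#' species threshold, pine otherwise.
#'
#' @param ndvi_values NDVI values of the crown's pixels.
#' @param thr a [thresholds()] list.
#' @param exclude optional logical of the same length: pixels to exclude
#'   from the mean (e.g. shaded, when the exclusion switch is on).
#' @return list with `species` ("oak"/"pine") and `mean_ndvi`.
#' @export
identify_species <- function(ndvi_values, thr = thresholds(), exclude = NULL) {
  v <- ndvi_values
  if (!is.null(exclude)) v <- v[!exclude]
  v <- v[is.finite(v)]
  m <- if (length(v)) mean(v) else NA_real_
  list(species = if (!is.na(m) && m >= thr$ndvi_species) "oak" else "pine",
       mean_ndvi = m)
}

#' Percent defoliation of a pine crown
#'
#' `100 * n_defoliated / (n_defoliated + n_non_defoliated)`: shaded
#' pixels are excluded from both numerator and denominator. A crown with
#' no usable (non-shaded) pixels yields `NA` and a flag.
#'
#' @param n_def,n_nondef,n_shaded pixel counts of the crown.
#' @param species species call for the crown; oaks are a rule error
#'   (they are excluded from defoliation assessment).
#' @return list with `defoliation_pct` and `flag_all_shaded`.
#' @export
defoliation_per_tree <- function(n_def, n_nondef, n_shaded = 0,
                                 species = "pine") {
  if (species == "oak")
    stop("defoliation is not assessed for oaks")
  den <- n_def + n_nondef
  if (den == 0)
    return(list(defoliation_pct = NA_real_, flag_all_shaded = TRUE))
  list(defoliation_pct = 100 * n_def / den, flag_all_shaded = FALSE)
}

#' Three-level defoliation class of a tree
#'
#' Cutpoints 15 and 85 percent; the boundary values belong to the
#' partially defoliated class.
#'
#' @param defoliation_pct percentage in `[0, 100]` (vectorized).
#' @return character vector: "non_defoliated", "partial", "complete";
#'   `NA` input propagates.
#' @export
classify_tree <- function(defoliation_pct) {
  ifelse(is.na(defoliation_pct), NA_character_,
         ifelse(defoliation_pct < 15, "non_defoliated",
                ifelse(defoliation_pct <= 85, "partial", "complete")))
}

#' Assess all delineated trees
#'
#' For each crown: species call from the crown-mean NDVI, pixel counts
#' from the class map, percent defoliation (pines) and the three-level
#' class ("oak" for oaks). Shaded pixels count towards the species mean
#' (switchable) but never towards the defoliation surface; nodata NDVI
#' pixels inside crowns are excluded from all counts.
#'
#' @param crown_label `defol_grid` of crown ids on the CHM grid (from
#'   [delineate_crowns()]).
#' @param ndvi,classmap `defol_grid`s on the multispectral grid
#'   ([compute_ndvi()], [classify_pixels()]).
#' @param thr a [thresholds()] list.
#' @param species_mean_excludes_shaded logical switch (default FALSE:
#'   the species mean uses all crown pixels).
#' @return data.table with one row per crown id: `tree_id`, `species`,
#'   `mean_ndvi`, `n_def`, `n_nondef`, `n_shaded`, `n_pixels`,
#'   `defoliation_pct` (NA for oaks and all-shaded crowns),
#'   `class_call`, `flag_all_shaded`.
#' @export
assess_trees <- function(crown_label, ndvi, classmap, thr = thresholds(),
                         species_mean_excludes_shaded = FALSE) {
  if (!grids_aligned(ndvi, classmap))
    stop("NDVI and class map are not co-registered")
  owner <- crown_ms_pixels(crown_label, ndvi)
  ids <- sort(unique(owner[owner > 0]))
  out <- vector("list", length(ids))
  nv <- ndvi$values; cm <- classmap$values
  for (k in seq_along(ids)) {
    id <- ids[k]
    sel <- owner == id
    ndvi_px <- nv[sel]
    cls <- cm[sel]
    valid <- is.finite(ndvi_px)
    cls <- cls[valid]; ndvi_px <- ndvi_px[valid]
    shaded <- cls == 3L
    sp <- identify_species(ndvi_px, thr,
                           exclude = if (species_mean_excludes_shaded) shaded)
    n_def <- sum(cls == 1L); n_nondef <- sum(cls == 2L)
    n_shaded <- sum(shaded)
    if (sp$species == "oak") {
      defol <- NA_real_; flag <- FALSE; call <- "oak"
    } else {
      dp <- defoliation_per_tree(n_def, n_nondef, n_shaded, sp$species)
      defol <- dp$defoliation_pct; flag <- dp$flag_all_shaded
      call <- classify_tree(defol)
    }
    out[[k]] <- data.table::data.table(
      tree_id = id, species = sp$species, mean_ndvi = sp$mean_ndvi,
      n_def = n_def, n_nondef = n_nondef, n_shaded = n_shaded,
      n_pixels = length(cls), defoliation_pct = defol,
      class_call = call, flag_all_shaded = flag)
  }
  data.table::rbindlist(out)
}
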