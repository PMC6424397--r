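# Vegetation indices and pixel classification.

#' Classification thresholds
#'
#' The three unitless thresholds of the pixel/tree classification:
#' NDVI below `ndvi_defoliation` marks a defoliated pixel, crown mean
#' NDVI at or above `ndvi_species` marks a holm oak, ExG below
#' `exg_shade` masks a shaded pixel. Defaults are the operational values
#' for the mixed pine-oak case this pipeline targets.
#'
#' @param ndvi_defoliation pixel-level defoliation threshold.
#' @param ndvi_species crown-mean species threshold.
#' @param exg_shade shade threshold on ExG.
#' @return a `thresholds` list.
#' @export
thresholds <- function(ndvi_defoliation = 0.27, ndvi_species = 0.42,
                       exg_shade = -0.06) {
  structure(list(ndvi_defoliation = ndvi_defoliation,
                 ndvi_species = ndvi_species, exg_shade = exg_shade),
            class = "thresholds")
}

#' Normalized difference vegetation index
#'
#' `(NIR - R) / (NIR + R)` per pixel; cells with a zero denominator
#' become nodata (`NA`).
#'
#' @param nir,red co-registered reflectance `defol_grid`s.
#' @return an NDVI `defol_grid` in `[-1, 1]`.
#' @export
compute_ndvi <- function(nir, red) {
  if (!grids_aligned(nir, red)) stop("NIR and red grids are not co-registered")
  den <- nir$values + red$values
  v <- (nir$values - red$values) / den
  v[den == 0] <- NA_real_
  grid_create(v, nir$origin, nir$cell_size, nir$nodata)
}

#' Excess green index on chromatic coordinates
#'
#' With `s = R + G + B`: `ExG = 2G/s - R/s - B/s`. Black pixels (`s = 0`)
#' are set to 0 — they can then never be classified as shaded — and their
#' count is reported via a message.
#'
#' @param r,g,b co-registered RGB `defol_grid`s.
#' @return an ExG `defol_grid` in `[-1, 2]` for non-negative inputs.
#' @export
compute_exg <- function(r, g, b) {
  if (!grids_aligned(r, g) || !grids_aligned(r, b))
    stop("RGB grids are not co-registered")
  s <- r$values + g$values + b$values
  v <- (2 * g$values - r$values - b$values) / s
  nblack <- sum(s == 0, na.rm = TRUE)
  if (nblack > 0) {
    message(sprintf("compute_exg: %d black pixels set to ExG = 0", nblack))
    v[s == 0] <- 0
  }
  grid_create(v, r$origin, r$cell_size, r$nodata)
}

#' Per-pixel three-class map: shaded / defoliated / non-defoliated
#'
#' Shade has precedence: a pixel with `ExG < exg_shade` is shaded
#' regardless of its NDVI. Otherwise NDVI below the defoliation
#' threshold marks a defoliated pixel, the rest are non-defoliated.
#' Pixels outside the optional mask (or with nodata NDVI) are background.
#'
#' Codes: 0 background/nodata, 1 defoliated, 2 non-defoliated, 3 shaded.
#'
#' @param ndvi,exg index grids from [compute_ndvi()]/[compute_exg()].
#' @param thr a [thresholds()] list.
#' @param mask optional logical matrix (TRUE = classify this pixel).
#' @return a `defol_grid` of integer class codes.
#' @export
classify_pixels <- function(ndvi, exg, thr = thresholds(), mask = NULL) {
  if (!grids_aligned(ndvi, exg)) stop("NDVI and ExG grids are not co-registered")
  v <- matrix(0L, nrow(ndvi$values), ncol(ndvi$values))
  use <- if (is.null(mask)) !is.na(ndvi$values) else mask & !is.na(ndvi$values)
  shaded <- use & !is.na(exg$values) & exg$values < thr$exg_shade
  defol <- use & !shaded & ndvi$values < thr$ndvi_defoliation
  nondef <- use & !shaded & !defol
  v[defol] <- 1L; v[nondef] <- 2L; v[shaded] <- 3L
  grid_create(v, ndvi$origin, ndvi$cell_size, ndvi$nodata)
}

#' Threshold sensitivity scan
#'
#' Evaluates two-class accuracy for every candidate threshold from `lo`
#' to `hi` in steps of `step`: units with `values >= t` are called
#' `hi_label`, the rest `lo_label`. Returns the accuracy-maximising
#' threshold (ties resolved to the lowest candidate) and the full curve.
#'
#' @param values numeric scores (per pixel or per tree).
#' @param labels reference class per unit; values equal to `hi_label`
#'   are the high-score class.
#' @param lo,hi scan range.
#' @param step scan increment (default 0.01).
#' @param hi_label label of the class expected above the threshold.
#' @return list with `best` (threshold), `curve` (data.table threshold /
#'   accuracy).
#' @export
scan_threshold <- function(values, labels, lo, hi, step = 0.01,
                           hi_label = NULL) {
  stopifnot(length(values) == length(labels), hi > lo)
  if (is.null(hi_label)) hi_label <- sort(unique(labels))[1]
  cand <- seq(lo, hi, by = step)
  is_hi <- labels == hi_label
  acc <- vapply(cand, function(t) mean((values >= t) == is_hi), numeric(1))
  data.table::data.table(threshold = cand, accuracy = acc) -> curve
  list(best = cand[which.max(acc)], curve = curve)
}

#' Unsupervised shade threshold from the ExG distribution
#'
#' One-dimensional 2-cluster k-means (10 restarts, seeded) on the ExG
#' values of crown pixels; the threshold is the midpoint of the two
#' cluster centers. This is the procedure that produces the default
#' shade threshold for a given scene.
#'
#' @param exg an ExG `defol_grid`.
#' @param mask optional logical matrix restricting to crown pixels.
#' @param seed RNG seed for the restarts.
#' @param max_n subsample cap for very large masks.
#' @return the shade threshold (numeric scalar).
#' @export
unsupervised_shade_threshold <- function(exg, mask = NULL, seed = 1L,
                                         max_n = 200000L) {
  v <- if (is.null(mask)) as.vector(exg$values) else exg$values[mask]
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("not enough ExG values for clustering")
  set.seed(seed)
  if (length(v) > max_n) v <- sample(v, max_n)
  km <- stats::kmeans(v, centers = 2, nstart = 10)
  mean(range(km$centers))
}
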