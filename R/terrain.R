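# Ground classification, DTM and CHM from a photogrammetric point cloud.

#' Ground-filter parameters
#'
#' Parameters of the progressive TIN densification ground filter, with
#' the conventional names: `step` is the seed-cell size, `bulge` caps the
#' roughness allowance, `spike` is the below-surface rejection distance,
#' `offset` the base acceptance distance above the surface. All metres.
#'
#' @param step,bulge,spike,offset positive numbers.
#' @return a `ground_params` list.
#' @export
ground_params <- function(step = 10, bulge = 0.5, spike = 1, offset = 0.05) {
  p <- list(step = step, bulge = bulge, spike = spike, offset = offset)
  if (any(unlist(p) <= 0)) stop("all ground parameters must be positive")
  class(p) <- "ground_params"
  p
}

# distance from each point to the nearest vertex, searching the 3x3
# neighbourhood of equally sized buckets holding at most one vertex each;
# Inf where no vertex is that close (callers cap the roughness there).
capped_vertex_dist <- function(px, py, vx, vy, cell) {
  kx <- floor(px / cell); ky <- floor(py / cell)
  vkey <- floor(vx / cell) * 1e6 + floor(vy / cell)
  best <- rep(Inf, length(px))
  for (dx in -1:1) for (dy in -1:1) {
    m <- match((kx + dx) * 1e6 + (ky + dy), vkey)
    ok <- !is.na(m)
    if (!any(ok)) next
    d <- sqrt((px[ok] - vx[m[ok]])^2 + (py[ok] - vy[m[ok]])^2)
    best[ok] <- pmin(best[ok], d)
  }
  best
}

# slope magnitude (m/m) of a surface grid by central differences
surface_slope <- function(g) {
  v <- g$values; s <- g$cell_size
  nr <- nrow(v); nc <- ncol(v)
  gx <- (v[, c(2:nc, nc)] - v[, c(1, 1:(nc - 1))]) / (2 * s)
  gy <- (v[c(2:nr, nr), ] - v[c(1, 1:(nr - 1)), ]) / (2 * s)
  grid_create(sqrt(gx^2 + gy^2), g$origin, s)
}

# TIN over (vx, vy, vz) rasterized to a surface covering the full cloud
# extent; NA fringes outside the hull are filled by the median filter so
# the surface is defined everywhere points fall.
tin_surface <- function(vx, vy, vz, xmin, ymin, xmax, ymax, cell = 1) {
  tmpl <- grid_empty(xmin - cell, ymin - cell, xmax + cell, ymax + cell, cell)
  tri <- delaunay(vx, vy)
  surf <- tin_rasterize(tri, vx, vy, vz, tmpl)
  if (anyNA(surf$values)) surf <- grid_fill_plane(surf)
  surf
}

#' Classify ground points by progressive TIN densification
#'
#' Seeds are the lowest point of each `step x step` cell; a seed lying
#' more than `spike` below the least-squares plane of its neighbouring
#' seeds is discarded. A Delaunay TIN over the seeds is then densified
#' iteratively: a point joins the ground set when its height above the
#' current surface is at most `offset + bulge * r`, where the roughness
#' term `r` is the local surface slope times the distance to the nearest
#' TIN vertex, capped at `bulge`. Accepted points are thinned onto a
#' halving grid and become TIN vertices for the next round, to a fixpoint
#' or at most 10 rounds. Points more than `spike` below the surface are
#' flagged as low noise.
#'
#' @param cloud point-cloud `data.table` with `x`, `y`, `z`.
#' @param params a [ground_params()].
#' @return the cloud with a `classification` column: 2 = ground,
#'   1 = non-ground, 7 = low noise.
#' @export
classify_ground <- function(cloud, params = ground_params()) {
  stopifnot(nrow(cloud) >= 3)
  x <- cloud$x; y <- cloud$y; z <- cloud$z
  xr <- range(x); yr <- range(y)
  if (diff(xr) <= 0 && diff(yr) <= 0)
    stop("degenerate point set: zero horizontal extent")

  # seeds: lowest point per step cell, halving the cell when too few
  step <- params$step
  repeat {
    dt <- data.table::data.table(
      i = seq_along(x),
      cell = floor((x - xr[1]) / step) * 1e6 + floor((y - yr[1]) / step), z = z)
    seeds <- dt[, .SD[which.min(z)], by = cell]$i
    if (length(seeds) >= 3 || step < 0.25) break
    step <- step / 2
  }
  # anchor the TIN at the data boundary: lowest point per segment of a
  # narrow strip along each edge, so the seed hull spans the full extent
  # (interior cell-lowest seeds rarely sit on the boundary itself)
  strip <- max(step / 10, 1)
  edge <- x - xr[1] < strip | xr[2] - x < strip |
    y - yr[1] < strip | yr[2] - y < strip
  if (any(edge)) {
    ei <- which(edge)
    seg <- floor((x[ei] - xr[1]) / step) * 1e6 + floor((y[ei] - yr[1]) / step)
    dt_e <- data.table::data.table(i = ei, cell = seg, z = z[ei])
    seeds <- union(seeds, dt_e[, .SD[which.min(z)], by = cell]$i)
  }
  if (length(seeds) < 3)
    stop("degenerate point set: fewer than 3 seed cells")

  # spike filter: drop seeds far below the plane of neighbouring seeds
  sx <- x[seeds]; sy <- y[seeds]; sz <- z[seeds]
  keep <- rep(TRUE, length(seeds))
  for (i in seq_along(seeds)) {
    nb <- which(abs(sx - sx[i]) <= 1.5 * step & abs(sy - sy[i]) <= 1.5 * step)
    nb <- setdiff(nb, i)
    if (length(nb) < 3) next
    fit <- stats::lm.fit(cbind(1, sx[nb], sy[nb]), sz[nb])
    pred <- sum(stats::coef(fit) * c(1, sx[i], sy[i]), na.rm = TRUE)
    if (is.finite(pred) && sz[i] < pred - params$spike) keep[i] <- FALSE
  }
  seeds <- seeds[keep]
  if (length(seeds) < 3)
    stop("degenerate point set: spike filter removed too many seeds")

  vx <- x[seeds]; vy <- y[seeds]; vz <- z[seeds]
  accepted_prev <- rep(FALSE, length(x))
  accepted <- accepted_prev
  low <- rep(FALSE, length(x))
  for (round in 1:10) {
    if (length(unique(paste(vx, vy))) < 3) break
    surf <- tryCatch(
      tin_surface(vx, vy, vz, xr[1], yr[1], xr[2], yr[2]),
      error = function(e) stop("degenerate point set: ", conditionMessage(e)))
    slope <- surface_slope(surf)
    dz <- z - grid_bilinear(surf, x, y)
    sl <- grid_value_at(slope, x, y)
    thin <- max(step / 2^(round - 1), 2)
    d <- capped_vertex_dist(x, y, vx, vy, thin)
    rough <- pmin(sl * d, params$bulge)
    rough[!is.finite(rough)] <- params$bulge
    tol <- params$offset + params$bulge * rough
    accepted <- is.finite(dz) & dz <= tol & dz >= -params$spike
    accepted[seeds] <- TRUE
    low <- is.finite(dz) & dz < -params$spike
    if (identical(accepted, accepted_prev)) break
    accepted_prev <- accepted
    # next vertex set: top of the accepted band, thinned per cell
    nxt <- max(step / 2^round, 2)
    dt <- data.table::data.table(
      i = which(accepted),
      cell = floor(x[accepted] / nxt) * 1e6 + floor(y[accepted] / nxt),
      z = z[accepted])
    vi <- dt[, .SD[which.max(z)], by = cell]$i
    vx <- x[vi]; vy <- y[vi]; vz <- z[vi]
  }
  out <- data.table::copy(data.table::as.data.table(cloud))
  out$classification <- ifelse(accepted, 2L, ifelse(low, 7L, 1L))
  out
}

#' Grid a DTM from ground-classified points
#'
#' Cell value = mean elevation of ground points in the cell; empty cells
#' are filled by TIN interpolation from the surrounding non-empty cell
#' centers (median-filter fallback for any remainder).
#'
#' @param cloud classified point cloud (needs `classification == 2` rows).
#' @param cell_size DTM cell size (m), default 1.
#' @return a `defol_grid` DTM.
#' @export
grid_dtm <- function(cloud, cell_size = 1) {
  g <- cloud[cloud$classification == 2L, ]
  if (nrow(g) == 0) stop("no ground-classified points")
  dtm <- grid_empty(min(g$x), min(g$y),
                    max(g$x) + 1e-9, max(g$y) + 1e-9, cell_size)
  rc <- grid_rowcol(dtm, g$x, g$y)
  dt <- data.table::data.table(row = rc$row, col = rc$col, z = g$z)
  dt <- dt[!is.na(row) & !is.na(col),
           list(z = mean(z)), by = c("row", "col")]
  dtm$values[cbind(dt$row, dt$col)] <- dt$z
  if (anyNA(dtm$values)) {
    filled <- which(!is.na(dtm$values), arr.ind = TRUE)
    if (nrow(filled) >= 3) {
      ctr <- grid_cell_center(dtm, filled[, 1], filled[, 2])
      zz <- dtm$values[filled]
      tri <- tryCatch(delaunay(ctr[, 1], ctr[, 2]), error = function(e) NULL)
      if (!is.null(tri)) {
        interp <- tin_rasterize(tri, ctr[, 1], ctr[, 2], zz, dtm)
        nas <- is.na(dtm$values)
        dtm$values[nas] <- interp$values[nas]
      }
    }
    if (anyNA(dtm$values))
      dtm <- grid_fill_plane(dtm)
  }
  dtm
}

#' Normalize point heights above ground
#'
#' Subtracts the bilinearly sampled DTM elevation from each point's z.
#' Negative normalized heights are clamped to 0; points falling outside
#' the DTM footprint are dropped with a message.
#'
#' @param cloud point cloud (any classification state).
#' @param dtm a `defol_grid` DTM.
#' @return the cloud with `z` replaced by height above ground.
#' @export
normalize_heights <- function(cloud, dtm) {
  ground_z <- grid_bilinear(dtm, cloud$x, cloud$y)
  keep <- is.finite(ground_z)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("normalize_heights: dropped %d points outside the DTM",
                    n_drop))
  out <- data.table::copy(data.table::as.data.table(cloud))[keep]
  out$z <- pmax(out$z - ground_z[keep], 0)
  out
}

#' Canopy height model from a normalized cloud
#'
#' Cell value = maximum normalized height of the points in the cell.
#' Empty cells are filled by an iterated 3x3 median of their non-empty
#' neighbours; cells still empty after that (outside the data) are 0.
#'
#' @param normalized height-normalized point cloud.
#' @param cell_size CHM cell size (m), default 0.5.
#' @param fill_passes cap on median-fill passes.
#' @return a non-negative `defol_grid` CHM.
#' @export
compute_chm <- function(normalized, cell_size = 0.5, fill_passes = 8L) {
  stopifnot(nrow(normalized) > 0)
  chm <- grid_empty(min(normalized$x), min(normalized$y),
                    max(normalized$x) + 1e-9, max(normalized$y) + 1e-9,
                    cell_size)
  rc <- grid_rowcol(chm, normalized$x, normalized$y)
  dt <- data.table::data.table(row = rc$row, col = rc$col, z = normalized$z)
  dt <- dt[!is.na(row) & !is.na(col),
           list(z = max(z)), by = c("row", "col")]
  chm$values[cbind(dt$row, dt$col)] <- dt$z
  chm <- grid_fill_median3(chm, min_neighbors = 3L, max_pass = fill_passes)
  chm$values[is.na(chm$values)] <- 0
  chm$values <- pmax(chm$values, 0)
  chm
}
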