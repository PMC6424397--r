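#' Single-band georeferenced grid
#'
#' The shared raster container of the pipeline. A `defol_grid` stores a
#' numeric matrix in map orientation: row 1 is the northmost row, column 1
#' the westmost. `origin` is the x,y of the *upper-left corner* of the
#' upper-left cell; cell (r, c) covers the half-open square
#' \code{[x0+(c-1)s, x0+cs) x (y0-rs, y0-(r-1)s]} and its center is at
#' \code{(x0+(c-0.5)s, y0-(r-0.5)s)}. Point sampling uses the pixel-center
#' convention throughout.
#'
#' @param values numeric matrix (rows = north to south).
#' @param origin length-2 numeric, x/y of the upper-left corner.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata value used as the nodata sentinel when writing; internally
#'   nodata cells are `NA`.
#' @return an object of class `defol_grid`.
#' @export
grid_create <- function(values, origin, cell_size, nodata = -9999) {
  stopifnot(is.matrix(values), length(origin) == 2, is.finite(cell_size),
            cell_size > 0)
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata),
    class = "defol_grid"
  )
}

#' Empty grid covering a rectangular extent
#'
#' @param xmin,ymin,xmax,ymax extent in metres.
#' @param cell_size cell size in metres.
#' @param fill initial cell value.
#' @inheritParams grid_create
#' @return a `defol_grid` whose upper-left corner is (`xmin`, `ymax`) and
#'   which covers at least the requested extent (dimensions are rounded up).
#' @export
grid_empty <- function(xmin, ymin, xmax, ymax, cell_size, fill = NA_real_,
                       nodata = -9999) {
  stopifnot(xmax > xmin, ymax > ymin, cell_size > 0)
  nc <- ceiling((xmax - xmin) / cell_size - 1e-9)
  nr <- ceiling((ymax - ymin) / cell_size - 1e-9)
  grid_create(matrix(fill, nrow = nr, ncol = nc), c(xmin, ymax), cell_size,
              nodata)
}

#' @export
print.defol_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<defol_grid> %d x %d cells @ %g m, origin (%.2f, %.2f)\n",
    nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: min %.3f, max %.3f, NA %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.defol_grid <- function(x) dim(x$values)

#' Grid extent as xmin/ymin/xmax/ymax
#' @param g a `defol_grid`.
#' @return named numeric vector.
#' @export
grid_extent <- function(g) {
  d <- dim(g$values)
  c(xmin = g$origin[1], ymin = g$origin[2] - d[1] * g$cell_size,
    xmax = g$origin[1] + d[2] * g$cell_size, ymax = g$origin[2])
}

#' Cell-center coordinates
#'
#' @param g a `defol_grid`.
#' @param rows,cols 1-based row/column indices (recycled together).
#' @return two-column matrix of x,y centers.
#' @export
grid_cell_center <- function(g, rows, cols) {
  cbind(x = g$origin[1] + (cols - 0.5) * g$cell_size,
        y = g$origin[2] - (rows - 0.5) * g$cell_size)
}

#' Row/column of the cell containing each point
#'
#' Points on a cell's east/south edge belong to the next cell (half-open
#' pixel convention).
#'
#' @param g a `defol_grid`.
#' @param x,y point coordinates (m).
#' @return data.frame with `row`, `col`; `NA` outside the grid.
#' @export
grid_rowcol <- function(g, x, y) {
  d <- dim(g$values)
  col <- floor((x - g$origin[1]) / g$cell_size) + 1L
  row <- floor((g$origin[2] - y) / g$cell_size) + 1L
  # points exactly on the top/left boundary belong to row/col 1
  row[y == g$origin[2]] <- 1L
  col[x == g$origin[1]] <- 1L
  bad <- row < 1L | row > d[1] | col < 1L | col > d[2] |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Nearest-cell value at points
#' @inheritParams grid_rowcol
#' @return numeric vector; `NA` outside the grid.
#' @export
grid_value_at <- function(g, x, y) {
  rc <- grid_rowcol(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Bilinear sample of a grid at points
#'
#' Interpolates between the four surrounding cell centers; inside the
#' half-cell margin the nearest valid centers are used (clamped indices),
#' so sampling is defined over the full grid footprint. Returns `NA`
#' outside the footprint or where all four support cells are `NA`.
#'
#' @inheritParams grid_rowcol
#' @return numeric vector of interpolated values.
#' @export
grid_bilinear <- function(g, x, y) {
  d <- dim(g$values); s <- g$cell_size
  # fractional cell-center coordinates (1-based)
  fc <- (x - g$origin[1]) / s + 0.5
  fr <- (g$origin[2] - y) / s + 0.5
  inside <- x >= g$origin[1] & x <= g$origin[1] + d[2] * s &
    y <= g$origin[2] & y >= g$origin[2] - d[1] * s &
    is.finite(x) & is.finite(y)
  c0 <- pmin(pmax(floor(fc), 1L), d[2] - 1L)
  r0 <- pmin(pmax(floor(fr), 1L), d[1] - 1L)
  if (d[2] == 1L) c0 <- rep(1L, length(x))
  if (d[1] == 1L) r0 <- rep(1L, length(x))
  tx <- pmin(pmax(fc - c0, 0), 1)
  ty <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1L, d[2]); r1 <- pmin(r0 + 1L, d[1])
  v <- g$values
  g00 <- v[cbind(r0, c0)]; g01 <- v[cbind(r0, c1)]
  g10 <- v[cbind(r1, c0)]; g11 <- v[cbind(r1, c1)]
  out <- (1 - ty) * ((1 - tx) * g00 + tx * g01) +
    ty * ((1 - tx) * g10 + tx * g11)
  out[!inside] <- NA_real_
  out
}

#' Check that two grids share origin, cell size and dimensions
#' @param a,b `defol_grid` objects.
#' @param tol coordinate tolerance in metres.
#' @return logical.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  all(abs(a$origin - b$origin) < tol) &&
    abs(a$cell_size - b$cell_size) < tol &&
    identical(dim(a$values), dim(b$values))
}

#' Mean-filter smoothing with an odd square window
#'
#' Window mean over available (non-NA) cells; edges use the truncated
#' window. Used to smooth the CHM ahead of treetop detection.
#'
#' @param g a `defol_grid`.
#' @param window odd window edge length in cells (default 3).
#' @return a smoothed `defol_grid`.
#' @export
grid_mean_filter <- function(g, window = 3L) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1L) return(g)
  h <- (window - 1L) / 2L
  v <- g$values
  num <- matrix(0, nrow(v), ncol(v))
  den <- matrix(0, nrow(v), ncol(v))
  vz <- v; vz[is.na(v)] <- 0
  vn <- !is.na(v)
  nr <- nrow(v); nc <- ncol(v)
  for (dr in -h:h) for (dc in -h:h) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)   # destination rows
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    num[rs, cs] <- num[rs, cs] + vz[rs - dr, cs - dc]
    den[rs, cs] <- den[rs, cs] + vn[rs - dr, cs - dc]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  grid_create(out, g$origin, g$cell_size, g$nodata)
}

#' Plane-extension fill of NA cells
#'
#' Each pass fits a least-squares plane through the valid cells of the
#' 5x5 window around an NA cell (when enough support exists) and
#' evaluates it at the cell center, so surfaces are extrapolated with
#' their local slope rather than flat. Remaining NA cells fall back to
#' the median fill. Used to extend TIN surfaces beyond the seed hull.
#'
#' @param g a `defol_grid`.
#' @param min_support minimum valid cells in the window to fit a plane.
#' @param max_pass safety cap on passes.
#' @return a filled `defol_grid`.
#' @export
grid_fill_plane <- function(g, min_support = 6L, max_pass = 256L) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  for (pass in seq_len(max_pass)) {
    nas <- which(is.na(v), arr.ind = TRUE)
    if (nrow(nas) == 0) break
    newv <- v
    filled <- FALSE
    for (i in seq_len(nrow(nas))) {
      r <- nas[i, 1]; c <- nas[i, 2]
      rs <- max(1, r - 2):min(nr, r + 2)
      cs <- max(1, c - 2):min(nc, c + 2)
      win <- v[rs, cs]
      ok <- which(!is.na(win), arr.ind = TRUE)
      if (nrow(ok) < min_support) next
      rr <- rs[ok[, 1]]; cc <- cs[ok[, 2]]
      zz <- win[ok]
      fit <- stats::lm.fit(cbind(1, rr - r, cc - c), zz)
      b <- fit$coefficients
      b[is.na(b)] <- 0
      newv[r, c] <- b[1]
      filled <- TRUE
    }
    v <- newv
    if (!filled) break
  }
  out <- grid_create(v, g$origin, g$cell_size, g$nodata)
  if (anyNA(out$values))
    out <- grid_fill_median3(out, min_neighbors = 1L, max_pass = 1024L)
  out
}

#' Iterative 3x3 median fill of NA cells
#'
#' Each pass replaces an NA cell that has at least `min_neighbors` non-NA
#' neighbours in its 3x3 window by their median; passes repeat until no NA
#' remains or nothing changes. Used to fill empty CHM cells.
#'
#' @param g a `defol_grid`.
#' @param min_neighbors minimum non-NA neighbours required to fill.
#' @param max_pass safety cap on passes.
#' @return a filled `defol_grid`.
#' @export
grid_fill_median3 <- function(g, min_neighbors = 3L, max_pass = 64L) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  for (pass in seq_len(max_pass)) {
    nas <- which(is.na(v), arr.ind = TRUE)
    if (nrow(nas) == 0) break
    filled <- FALSE
    newv <- v
    for (i in seq_len(nrow(nas))) {
      r <- nas[i, 1]; c <- nas[i, 2]
      nb <- v[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
      nb <- nb[!is.na(nb)]
      if (length(nb) >= min_neighbors) {
        newv[r, c] <- stats::median(nb)
        filled <- TRUE
      }
    }
    v <- newv
    if (!filled) break
  }
  grid_create(v, g$origin, g$cell_size, g$nodata)
}
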