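# ---- polygons ----------------------------------------------------------
# A polygon is a two-column numeric matrix of vertices (x, y), implicitly
# closed, in either winding order.

#' Signed and absolute polygon area
#'
#' Shoelace formula; `polygon_area()` returns the absolute area.
#'
#' @param poly two-column matrix of vertices.
#' @return area in squared input units.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Points-in-polygon test
#'
#' Even-odd ray casting, vectorized over points. Boundary points may fall
#' on either side; callers needing exact boundary handling should use the
#' clipping routines.
#'
#' @param x,y point coordinates.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y))
    if (any(crosses)) {
      xin <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
      inside <- xor(inside, crosses & (x < xin))
    }
    j <- i
  }
  inside
}

is_convex_polygon <- function(poly, tol = 1e-12) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1); nx2 <- c(3:n, 1, 2)
  cr <- (poly[nxt, 1] - poly[, 1]) * (poly[nx2, 2] - poly[nxt, 2]) -
    (poly[nxt, 2] - poly[, 2]) * (poly[nx2, 1] - poly[nxt, 1])
  all(cr >= -tol) || all(cr <= tol)
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' @param subject two-column vertex matrix (any simple polygon).
#' @param clip two-column vertex matrix; must be convex.
#' @return the clipped polygon (possibly with zero rows).
#' @export
clip_polygon_convex <- function(subject, clip) {
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    # keep points left of edge a->b (clip is CCW)
    ox <- out[, 1]; oy <- out[, 2]
    side <- (b[1] - a[1]) * (oy - a[2]) - (b[2] - a[2]) * (ox - a[1])
    n <- nrow(out)
    res <- matrix(numeric(0), ncol = 2)
    prev <- n
    for (k in seq_len(n)) {
      cur_in <- side[k] >= 0
      prev_in <- side[prev] >= 0
      if (cur_in != prev_in) {
        t <- side[prev] / (side[prev] - side[k])
        res <- rbind(res, out[prev, ] + t * (out[k, ] - out[prev, ]))
      }
      if (cur_in) res <- rbind(res, out[k, ])
      prev <- k
    }
    out <- res
  }
  out
}

#' Intersection area of two polygons
#'
#' Exact (Sutherland-Hodgman) when at least one polygon is convex;
#' otherwise estimated by sampling cell centers on a fine grid over the
#' bounding-box overlap.
#'
#' @param p,q two-column vertex matrices.
#' @param grid_n sampling resolution per axis for the non-convex fallback.
#' @return intersection area.
#' @export
polygon_intersection_area <- function(p, q, grid_n = 400L) {
  if (is_convex_polygon(q)) {
    r <- clip_polygon_convex(p, q)
    return(if (nrow(r) < 3) 0 else polygon_area(r))
  }
  if (is_convex_polygon(p)) {
    r <- clip_polygon_convex(q, p)
    return(if (nrow(r) < 3) 0 else polygon_area(r))
  }
  xmin <- max(min(p[, 1]), min(q[, 1])); xmax <- min(max(p[, 1]), max(q[, 1]))
  ymin <- max(min(p[, 2]), min(q[, 2])); ymax <- min(max(p[, 2]), max(q[, 2]))
  if (xmax <= xmin || ymax <= ymin) return(0)
  xs <- seq(xmin, xmax, length.out = grid_n + 1L); xs <- (xs[-1] + xs[-length(xs)]) / 2
  ys <- seq(ymin, ymax, length.out = grid_n + 1L); ys <- (ys[-1] + ys[-length(ys)]) / 2
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  hit <- point_in_polygon(gx, gy, p) & point_in_polygon(gx, gy, q)
  mean(hit) * (xmax - xmin) * (ymax - ymin)
}

#' Regular-polygon approximation of a disc
#'
#' @param center length-2 numeric.
#' @param radius disc radius.
#' @param n number of vertices (default 64).
#' @return two-column vertex matrix (CCW).
#' @export
disc_polygon <- function(center, radius, n = 64L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
}

# ---- Delaunay triangulation (Bowyer-Watson) ----------------------------

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction with a super-triangle; the
#' bad-triangle search is vectorized over triangles so point sets of a few
#' thousand vertices triangulate in seconds. Nearly-degenerate inputs
#' (all points collinear) raise an error.
#'
#' @param x,y point coordinates (no duplicates).
#' @return integer matrix with one row per triangle, columns `a`,`b`,`c`
#'   indexing into the input points.
#' @export
delaunay <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 points for triangulation")
  rngx <- range(x); rngy <- range(y)
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1)
  cx <- mean(rngx); cy <- mean(rngy)
  # super-triangle far outside the data
  px <- c(x, cx - 30 * span, cx + 30 * span, cx)
  py <- c(y, cy - 20 * span, cy - 20 * span, cy + 30 * span)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  cap <- max(64L, 8L * n)
  tri <- matrix(NA_integer_, nrow = cap, ncol = 3)
  ccx <- numeric(cap); ccy <- numeric(cap); cr2 <- numeric(cap)
  alive <- logical(cap)
  ntri <- 0L

  circum <- function(a, b, c) {
    ax <- px[a]; ay <- py[a]; bx <- px[b]; by <- py[b]; cxx <- px[c]; cyy <- py[c]
    d <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
    if (abs(d) < 1e-12 * span * span) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
             (cxx^2 + cyy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
             (cxx^2 + cyy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  add_tri <- function(a, b, c) {
    cc <- circum(a, b, c)
    if (is.null(cc)) return(invisible(NULL))  # degenerate sliver: skip
    ntri <<- ntri + 1L
    if (ntri > nrow(tri)) {
      grow <- nrow(tri)
      tri <<- rbind(tri, matrix(NA_integer_, grow, 3))
      ccx <<- c(ccx, numeric(grow)); ccy <<- c(ccy, numeric(grow))
      cr2 <<- c(cr2, numeric(grow)); alive <<- c(alive, logical(grow))
    }
    tri[ntri, ] <<- c(a, b, c)
    ccx[ntri] <<- cc[1]; ccy[ntri] <<- cc[2]; cr2[ntri] <<- cc[3]
    alive[ntri] <<- TRUE
    invisible(NULL)
  }
  add_tri(s1, s2, s3)

  ord <- order(x + y)  # spatially coherent insertion order
  for (ip in ord) {
    idx <- which(alive[seq_len(ntri)])
    bad <- idx[(px[ip] - ccx[idx])^2 + (py[ip] - ccy[idx])^2 <= cr2[idx] *
                 (1 + 1e-12)]
    if (length(bad) == 0) next  # duplicate/degenerate point
    # boundary of the cavity: edges appearing exactly once among bad tris
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- key %in% names(which(table(key) == 1))
    alive[bad] <- FALSE
    eb <- e[once, , drop = FALSE]
    for (k in seq_len(nrow(eb))) add_tri(eb[k, 1], eb[k, 2], ip)
  }
  keep <- which(alive[seq_len(ntri)])
  out <- tri[keep, , drop = FALSE]
  out <- out[rowSums(out > n) == 0, , drop = FALSE]
  if (nrow(out) == 0) stop("degenerate point set: no valid triangulation")
  colnames(out) <- c("a", "b", "c")
  out
}

#' Rasterize a TIN to a grid by planar interpolation
#'
#' Each triangle's plane is evaluated at the covered cell centers; cells
#' outside the triangulation stay `NA`.
#'
#' @param tri triangle index matrix from [delaunay()].
#' @param x,y,z vertex coordinates and values.
#' @param template a `defol_grid` supplying geometry (values ignored).
#' @return a `defol_grid` of interpolated values.
#' @export
tin_rasterize <- function(tri, x, y, z, template) {
  g <- template
  d <- dim(g$values); s <- g$cell_size
  out <- matrix(NA_real_, d[1], d[2])
  xs <- g$origin[1] + (seq_len(d[2]) - 0.5) * s
  ys <- g$origin[2] - (seq_len(d[1]) - 0.5) * s
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; cc <- tri[t, 3]
    tx <- x[c(a, b, cc)]; ty <- y[c(a, b, cc)]; tz <- z[c(a, b, cc)]
    cr <- which(xs >= min(tx) - s & xs <= max(tx) + s)
    rr <- which(ys >= min(ty) - s & ys <= max(ty) + s)
    if (!length(cr) || !length(rr)) next
    gx <- rep(xs[cr], each = length(rr))
    gy <- rep(ys[rr], times = length(cr))
    det <- (ty[2] - ty[3]) * (tx[1] - tx[3]) + (tx[3] - tx[2]) * (ty[1] - ty[3])
    if (abs(det) < 1e-12) next
    l1 <- ((ty[2] - ty[3]) * (gx - tx[3]) + (tx[3] - tx[2]) * (gy - ty[3])) / det
    l2 <- ((ty[3] - ty[1]) * (gx - tx[3]) + (tx[1] - tx[3]) * (gy - ty[3])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    zi <- l1 * tz[1] + l2 * tz[2] + l3 * tz[3]
    idx <- cbind(rep(rr, times = length(cr))[inside],
                 rep(cr, each = length(rr))[inside])
    out[idx] <- zi[inside]
  }
  grid_create(out, g$origin, s, g$nodata)
}

# ---- nearest-neighbour search on a bucket grid -------------------------

#' Nearest reference point for each query point
#'
#' Bucketed linear search: reference points are hashed into square cells
#' of size `cell`; each query scans outward ring by ring until a neighbour
#' is confirmed nearest. Suitable for the densities this package works at.
#'
#' @param qx,qy query coordinates.
#' @param rx,ry reference coordinates.
#' @param cell bucket edge length; default pitches buckets to ~1 ref/cell.
#' @return list with `index` (into the reference set) and `dist`.
#' @export
nearest_neighbor <- function(qx, qy, rx, ry, cell = NULL) {
  nref <- length(rx)
  stopifnot(nref >= 1)
  if (is.null(cell)) {
    area <- max(diff(range(rx)), 1e-9) * max(diff(range(ry)), 1e-9)
    cell <- max(sqrt(area / nref), 1e-6)
  }
  x0 <- min(rx, qx); y0 <- min(ry, qy)
  rcx <- floor((rx - x0) / cell); rcy <- floor((ry - y0) / cell)
  key <- paste(rcx, rcy)
  buckets <- split(seq_len(nref), key)
  nq <- length(qx)
  best_i <- integer(nq); best_d <- numeric(nq)
  qcx <- floor((qx - x0) / cell); qcy <- floor((qy - y0) / cell)
  for (i in seq_len(nq)) {
    bd2 <- Inf; bi <- NA_integer_
    ring <- 0L
    repeat {
      cand <- integer(0)
      for (dx in -ring:ring) for (dy in -ring:ring) {
        if (max(abs(dx), abs(dy)) != ring) next
        b <- buckets[[paste(qcx[i] + dx, qcy[i] + dy)]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      if (length(cand)) {
        d2 <- (rx[cand] - qx[i])^2 + (ry[cand] - qy[i])^2
        k <- which.min(d2)
        if (d2[k] < bd2) { bd2 <- d2[k]; bi <- cand[k] }
      }
      # once a candidate is found, one extra ring guarantees correctness
      if (!is.na(bi) && (ring * cell)^2 >= bd2) break
      ring <- ring + 1L
      if (ring > 1e4) break
    }
    best_i[i] <- bi; best_d[i] <- sqrt(bd2)
  }
  list(index = best_i, dist = best_d)
}
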