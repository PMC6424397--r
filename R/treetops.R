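# Individual tree detection and crown delineation on the CHM.

# min/max filters over an odd square window (NA-safe, truncated edges)
window_extreme <- function(v, window, fun = pmax, init = -Inf) {
  h <- (window - 1L) / 2L
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(init, nr, nc)
  vv <- v; vv[is.na(vv)] <- init
  for (dr in -h:h) for (dc in -h:h) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- fun(out[rs, cs], vv[rs - dr, cs - dc])
  }
  out
}

#' Detect treetops on a CHM by the local-maximum rule
#'
#' The CHM is smoothed by a square window mean; a pixel is an apex when
#' its smoothed value is at least every other value in the search window
#' and either strictly exceeds one of them or is the representative
#' (top-left pixel in row-major order) of a connected equal-valued
#' plateau, and the smoothed value reaches `min_height`. Apexes are
#' reported with the original (unsmoothed) CHM height.
#'
#' @param chm a `defol_grid` canopy height model.
#' @param smooth_window,search_window odd window sizes in cells
#'   (default 3).
#' @param min_height minimum smoothed apex height (m); default 2 excludes
#'   shrubs and terrain artefacts.
#' @return data.table with `tree_id`, `row`, `col`, `x`, `y`, `height`;
#'   zero rows when the CHM holds no canopy.
#' @export
detect_treetops <- function(chm, smooth_window = 3L, search_window = 3L,
                            min_height = 2) {
  stopifnot(smooth_window >= 3, smooth_window %% 2 == 1,
            search_window >= 3, search_window %% 2 == 1)
  sm <- grid_mean_filter(chm, smooth_window)$values
  wmax <- window_extreme(sm, search_window, pmax, -Inf)
  wmin <- window_extreme(sm, search_window, pmin, Inf)
  cand <- !is.na(sm) & sm >= wmax & sm >= min_height
  apex <- cand & (wmin < wmax)
  # plateau candidates: locally constant windows. Each one delegates to
  # the top-left (row-major first) pixel of its connected equal-valued
  # plateau, which becomes the apex when it itself is a candidate.
  plat <- which(cand & (wmin >= wmax), arr.ind = TRUE)
  if (nrow(plat) > 0) {
    nr <- nrow(sm); nc <- ncol(sm)
    seen <- matrix(FALSE, nr, nc)
    ord <- order(plat[, 1], plat[, 2])
    for (k in ord) {
      r0 <- plat[k, 1]; c0 <- plat[k, 2]
      if (seen[r0, c0]) next
      # flood the connected equal-valued plateau (8-neighbour)
      val <- sm[r0, c0]
      comp <- matrix(c(r0, c0), 1, 2)
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r < 1 || r > nr || c < 1 || c > nc || seen[r, c]) next
          if (!is.na(sm[r, c]) && sm[r, c] == val) {
            seen[r, c] <- TRUE
            comp <- rbind(comp, c(r, c))
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
      first <- comp[order(comp[, 1], comp[, 2])[1], ]
      if (cand[first[1], first[2]]) apex[first[1], first[2]] <- TRUE
    }
  }
  hits <- which(apex, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.table::data.table(tree_id = integer(0), row = integer(0),
                                  col = integer(0), x = numeric(0),
                                  y = numeric(0), height = numeric(0)))
  }
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  ctr <- grid_cell_center(chm, hits[, 1], hits[, 2])
  data.table::data.table(
    tree_id = seq_len(nrow(hits)), row = hits[, 1], col = hits[, 2],
    x = ctr[, 1], y = ctr[, 2], height = chm$values[hits])
}

# trace the outer outline polygon of a 4-connected pixel set
pixel_outline <- function(cells, grid) {
  s <- grid$cell_size; x0 <- grid$origin[1]; y0 <- grid$origin[2]
  key <- cells[, 1] * 1e6 + cells[, 2]
  inset <- function(r, c) (r * 1e6 + c) %in% key
  # directed boundary edges, interior kept on the left (CCW outer ring)
  from <- list(); to <- list()
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    xl <- x0 + (c - 1) * s; xr <- xl + s
    yt <- y0 - (r - 1) * s; yb <- yt - s
    if (!inset(r - 1, c)) { from <- c(from, list(c(xl, yt))); to <- c(to, list(c(xr, yt))) }
    if (!inset(r + 1, c)) { from <- c(from, list(c(xr, yb))); to <- c(to, list(c(xl, yb))) }
    if (!inset(r, c - 1)) { from <- c(from, list(c(xl, yb))); to <- c(to, list(c(xl, yt))) }
    if (!inset(r, c + 1)) { from <- c(from, list(c(xr, yt))); to <- c(to, list(c(xr, yb))) }
  }
  fm <- do.call(rbind, from); tm <- do.call(rbind, to)
  fkey <- paste(round(fm[, 1] / s * 2), round(fm[, 2] / s * 2))
  used <- rep(FALSE, nrow(fm))
  rings <- list()
  for (start in seq_len(nrow(fm))) {
    if (used[start]) next
    ring <- list(fm[start, ])
    cur <- start
    repeat {
      used[cur] <- TRUE
      nxt_key <- paste(round(tm[cur, 1] / s * 2), round(tm[cur, 2] / s * 2))
      nxt <- which(fkey == nxt_key & !used)
      if (!length(nxt)) break
      cur <- nxt[1]
      ring[[length(ring) + 1L]] <- fm[cur, ]
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  areas <- vapply(rings, function(r) if (nrow(r) >= 3) polygon_area(r) else 0,
                  numeric(1))
  rings[[which.max(areas)]]
}

#' Delineate individual crowns around detected treetops
#'
#' Every CHM pixel with height > 0 is assigned to the Voronoi cell of the
#' nearest apex (ties go to the lowest tree id). Within a cell, pixels
#' stay in the crown when their height reaches `exclusion_fraction` times
#' the apex height and they lie within `max_radius_m` of the apex; the
#' crown is then reduced to the 4-connected component containing the
#' apex and its outline polygon is traced.
#'
#' @param chm a `defol_grid` CHM.
#' @param tops treetop table from [detect_treetops()].
#' @param exclusion_fraction minimum height as a fraction of apex height.
#' @param max_radius_m maximum crown radius (m).
#' @return list with `crowns` (list of `defol_crown`: tree_id, cells,
#'   area, polygon) and `label` (a `defol_grid` of tree ids, 0 = none).
#' @export
delineate_crowns <- function(chm, tops, exclusion_fraction = 0.3,
                             max_radius_m = 6) {
  stopifnot(nrow(tops) >= 1)
  d <- dim(chm$values)
  bad <- tops$row < 1 | tops$row > d[1] | tops$col < 1 | tops$col > d[2] |
    is.na(tops$row) | is.na(tops$col)
  if (any(bad))
    stop("apex outside CHM for tree id(s): ",
         paste(tops$tree_id[bad], collapse = ", "))
  s <- chm$cell_size
  xs <- chm$origin[1] + (seq_len(d[2]) - 0.5) * s
  ys <- chm$origin[2] - (seq_len(d[1]) - 0.5) * s
  px <- matrix(rep(xs, each = d[1]), d[1], d[2])
  py <- matrix(rep(ys, times = d[2]), d[1], d[2])
  best_d2 <- matrix(Inf, d[1], d[2])
  owner <- matrix(0L, d[1], d[2])
  for (i in order(tops$tree_id, decreasing = TRUE)) {
    d2 <- (px - tops$x[i])^2 + (py - tops$y[i])^2
    upd <- d2 <= best_d2    # <=: later (lower) ids win ties
    owner[upd] <- tops$tree_id[i]
    best_d2[upd] <- d2[upd]
  }
  v <- chm$values
  apex_h <- tops$height[match(owner, tops$tree_id)]
  keep <- !is.na(v) & v > 0 & owner > 0 &
    v >= exclusion_fraction * matrix(apex_h, d[1], d[2]) &
    best_d2 <= max_radius_m^2
  owner[!keep] <- 0L
  label <- matrix(0L, d[1], d[2])
  crowns <- vector("list", nrow(tops))
  for (i in seq_len(nrow(tops))) {
    id <- tops$tree_id[i]
    r0 <- tops$row[i]; c0 <- tops$col[i]
    cells <- flood_component(owner == id, r0, c0)
    if (is.null(cells)) cells <- matrix(c(r0, c0), 1, 2)
    label[cells] <- id
    crowns[[i]] <- structure(
      list(tree_id = id, cells = cells, apex = c(r0, c0),
           area = nrow(cells) * s^2,
           polygon = pixel_outline(cells, chm)),
      class = "defol_crown")
  }
  list(crowns = crowns,
       label = grid_create(label, chm$origin, s))
}

# 4-connected component of TRUE cells containing (r0, c0); NULL when the
# start cell itself is FALSE
flood_component <- function(mask, r0, c0) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!mask[r0, c0]) return(NULL)
  lab <- matrix(FALSE, nr, nc)
  lab[r0, c0] <- TRUE
  frontier <- matrix(c(r0, c0), 1, 2)
  while (nrow(frontier) > 0) {
    nxt <- rbind(cbind(frontier[, 1] - 1L, frontier[, 2]),
                 cbind(frontier[, 1] + 1L, frontier[, 2]),
                 cbind(frontier[, 1], frontier[, 2] - 1L),
                 cbind(frontier[, 1], frontier[, 2] + 1L))
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= nr & nxt[, 2] >= 1 & nxt[, 2] <= nc
    nxt <- nxt[ok, , drop = FALSE]
    ok <- mask[nxt] & !lab[nxt]
    nxt <- unique(nxt[ok, , drop = FALSE])
    if (nrow(nxt) == 0) break
    lab[nxt] <- TRUE
    frontier <- nxt
  }
  which(lab, arr.ind = TRUE)
}

#' Sørensen overlap between two crown delineations
#'
#' `SC = 2A / (2A + B + C)` with `A` the area delineated by both, `B` the
#' area only in the first input, `C` the area only in the reference.
#' Inputs may be `defol_crown` objects (their outline polygon is used) or
#' two-column vertex matrices.
#'
#' @param crown a `defol_crown` or polygon matrix.
#' @param reference_polygon a `defol_crown` or polygon matrix.
#' @return list with `A`, `B`, `C` (m²) and `SC`.
#' @export
sorensen <- function(crown, reference_polygon) {
  p <- if (inherits(crown, "defol_crown")) crown$polygon else crown
  q <- if (inherits(reference_polygon, "defol_crown"))
    reference_polygon$polygon else reference_polygon
  a_p <- polygon_area(p); a_q <- polygon_area(q)
  A <- polygon_intersection_area(p, q)
  A <- min(A, a_p, a_q)
  B <- a_p - A; C <- a_q - A
  SC <- if (2 * A + B + C == 0) 0 else 2 * A / (2 * A + B + C)
  list(A = A, B = B, C = C, SC = SC)
}

#' Match detected treetops to reference trees
#'
#' Greedy one-to-one matching by increasing apex distance, accepting
#' pairs closer than `max_dist`.
#'
#' @param detected data.frame with `x`, `y` (and `tree_id`).
#' @param reference data.frame with `x`, `y` (and `tree_id`).
#' @param max_dist maximum pairing distance (m), default 1.
#' @return list with `pairs` (data.table detected_id/reference_id/dist),
#'   `recall`, `precision`.
#' @export
match_trees <- function(detected, reference, max_dist = 1) {
  nd <- nrow(detected); nref <- nrow(reference)
  if (nd == 0 || nref == 0)
    return(list(pairs = data.table::data.table(), recall = 0, precision = 0))
  dmat <- outer(detected$x, reference$x, "-")^2 +
    outer(detected$y, reference$y, "-")^2
  pairs <- list()
  repeat {
    m <- which.min(dmat)
    if (!length(m) || dmat[m] > max_dist^2) break
    i <- (m - 1) %% nd + 1; j <- (m - 1) %/% nd + 1
    pairs[[length(pairs) + 1L]] <- data.table::data.table(
      detected_id = detected$tree_id[i], reference_id = reference$tree_id[j],
      dist = sqrt(dmat[m]))
    dmat[i, ] <- Inf; dmat[, j] <- Inf
  }
  pairs <- data.table::rbindlist(pairs)
  list(pairs = pairs,
       recall = nrow(pairs) / nref,
       precision = nrow(pairs) / nd)
}
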