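test_that("Delaunay triangulations satisfy the empty-circumcircle property", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:80, 1)
    x <- runif(n) * 10; y <- runif(n) * 10
    tri <- delaunay(x, y)
    # every triangle's circumcircle excludes all other points
    for (t in seq_len(nrow(tri))) {
      i <- tri[t, ]
      ax <- x[i[1]]; ay <- y[i[1]]; bx <- x[i[2]]; by <- y[i[2]]
      cx <- x[i[3]]; cy <- y[i[3]]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      r2 <- (ux - ax)^2 + (uy - ay)^2
      inside <- (x - ux)^2 + (y - uy)^2 < r2 * (1 - 1e-9)
      inside[i] <- FALSE
      expect_false(any(inside))
    }
    # triangles tile the convex hull: areas sum to the hull area
    hull <- chull(x, y)
    hull_area <- polygon_area(cbind(x[hull], y[hull]))
    tri_area <- sum(vapply(seq_len(nrow(tri)), function(t)
      polygon_area(cbind(x[tri[t, ]], y[tri[t, ]])), numeric(1)))
    expect_equal(tri_area, hull_area, tolerance = 1e-8)
  }
})

test_that("degenerate (collinear) point sets raise a geometry error", {
  expect_error(delaunay(1:5, 2 * (1:5) + 1), "degenerate")
  expect_error(delaunay(1, 1), "at least 3")
})

test_that("TIN rasterization reproduces a planar field", {
  set.seed(3)
  x <- runif(30, 0, 10); y <- runif(30, 0, 10)
  z <- 1.5 * x - 0.5 * y + 2
  tri <- delaunay(x, y)
  g <- tin_rasterize(tri, x, y, z, grid_empty(0, 0, 10, 10, 0.5))
  d <- dim(g$values)
  ctr <- grid_cell_center(g, rep(seq_len(d[1]), times = d[2]),
                          rep(seq_len(d[2]), each = d[1]))
  expect_v <- 1.5 * ctr[, 1] - 0.5 * ctr[, 2] + 2
  inside <- !is.na(as.vector(g$values))
  expect_gt(mean(inside), 0.5)
  expect_equal(as.vector(g$values)[inside], expect_v[inside],
               tolerance = 1e-8)
})

test_that("polygon area and point-in-polygon agree with closed forms", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 2)
  disc <- disc_polygon(c(1, 1), 1, n = 256)
  expect_equal(polygon_area(disc), pi, tolerance = 1e-3)
  expect_true(point_in_polygon(1, 0.5, sq))
  expect_false(point_in_polygon(3, 0.5, sq))
  expect_true(point_in_polygon(1, 1.2, disc))
})

test_that("convex clipping computes exact intersection areas", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  # unit square clipped by the right triangle under x + y = 1
  out <- clip_polygon_convex(sq, tri)
  expect_equal(polygon_area(out), 0.5)
  expect_equal(polygon_intersection_area(sq, tri), 0.5)
  # the square fully inside a larger triangle is returned intact
  expect_equal(polygon_intersection_area(sq, cbind(c(0, 2, 0), c(0, 0, 2))), 1)
  # disjoint polygons intersect in nothing
  far <- sq; far[, 1] <- far[, 1] + 5
  expect_equal(polygon_intersection_area(sq, far), 0)
})

test_that("nearest_neighbor matches brute force on random sets", {
  for (seed in 1:3) {
    set.seed(seed)
    rx <- runif(40) * 50; ry <- runif(40) * 50
    qx <- runif(25) * 50; qy <- runif(25) * 50
    nn <- nearest_neighbor(qx, qy, rx, ry)
    for (i in seq_along(qx)) {
      d2 <- (rx - qx[i])^2 + (ry - qy[i])^2
      expect_equal(nn$index[i], which.min(d2))
      expect_equal(nn$dist[i], sqrt(min(d2)))
    }
  }
})
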