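# File formats: LAS 1.2 / XYZ point clouds, GeoJSON vectors, CSV tables.

#' Read a point cloud (LAS 1.2+ or XYZ text)
#'
#' LAS files (point formats 0/1) are parsed directly; text files are
#' read as delimited x/y/z (with optional `classification`), with or
#' without a header line.
#'
#' @param path `.las` file or delimited text (`.csv`, `.txt`, `.xyz`).
#' @return point-cloud `data.table` with `x`, `y`, `z` and, when
#'   present, `classification`.
#' @export
read_point_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "las") return(read_las(path))
  dt <- data.table::fread(path)
  if (!all(c("x", "y", "z") %in% tolower(names(dt)))) {
    stopifnot(ncol(dt) >= 3)
    names(dt)[1:3] <- c("x", "y", "z")
  } else {
    names(dt) <- tolower(names(dt))
  }
  dt
}

#' Write a point cloud
#'
#' @param cloud point-cloud `data.table`.
#' @param path `.las` for LAS 1.2 binary, anything else for XYZ CSV.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  if (tolower(tools::file_ext(path)) == "las") return(write_las(cloud, path))
  cols <- intersect(c("x", "y", "z", "classification"), names(cloud))
  data.table::fwrite(cloud[, cols, with = FALSE], path)
  invisible(path)
}

read_las <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  readBin(con, "raw", 2 + 2 + 16)           # source id, encoding, GUID
  ver <- readBin(con, "integer", 2, size = 1)
  if (ver[1] != 1) stop("unsupported LAS version ", ver[1], ".", ver[2])
  readBin(con, "raw", 64)                   # system id + software
  readBin(con, "integer", 2, size = 2, signed = FALSE)  # day, year
  readBin(con, "integer", 1, size = 2, signed = FALSE)  # header size
  off <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)      # n VLRs
  fmt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  reclen <- readBin(con, "integer", 1, size = 2, signed = FALSE)
  npts <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 5, size = 4)      # by return
  sc <- readBin(con, "double", 3)
  offs <- readBin(con, "double", 3)
  if (!fmt %in% c(0L, 1L)) stop("unsupported LAS point format ", fmt)
  seek(con, off)
  raw <- readBin(con, "raw", npts * reclen)
  m <- matrix(raw, nrow = reclen)
  int32 <- function(rows) readBin(as.raw(m[rows, ]), "integer", npts, size = 4)
  x <- int32(1:4) * sc[1] + offs[1]
  y <- int32(5:8) * sc[2] + offs[2]
  z <- int32(9:12) * sc[3] + offs[3]
  cls <- as.integer(m[16, ])
  data.table::data.table(x = x, y = y, z = z, classification = cls)
}

write_las <- function(cloud, path) {
  n <- nrow(cloud)
  sc <- c(0.001, 0.001, 0.001)
  offs <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("LASF", con, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)                 # source id, encoding
  writeBin(raw(16), con)                              # GUID
  writeBin(c(1L, 2L), con, size = 1)                  # version 1.2
  writeBin(charToRaw(formatC("defoliatr", width = 32, flag = "-")), con)
  writeBin(charToRaw(formatC("defoliatr", width = 32, flag = "-")), con)
  writeBin(c(1L, 2026L), con, size = 2)               # day, year
  writeBin(227L, con, size = 2)                       # header size
  writeBin(227L, con, size = 4)                       # point data offset
  writeBin(0L, con, size = 4)                         # no VLRs
  writeBin(0L, con, size = 1)                         # point format 0
  writeBin(20L, con, size = 2)                        # record length
  writeBin(n, con, size = 4)
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)       # points by return
  writeBin(c(sc, offs,
             max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
             max(cloud$z), min(cloud$z)), con)
  xi <- as.integer(round((cloud$x - offs[1]) / sc[1]))
  yi <- as.integer(round((cloud$y - offs[2]) / sc[2]))
  zi <- as.integer(round((cloud$z - offs[3]) / sc[3]))
  cls <- if ("classification" %in% names(cloud))
    as.integer(cloud$classification) else rep(0L, n)
  rec <- matrix(as.raw(0), nrow = 20, ncol = n)
  rec[1:4, ] <- matrix(writeBin(xi, raw(), size = 4), nrow = 4)
  rec[5:8, ] <- matrix(writeBin(yi, raw(), size = 4), nrow = 4)
  rec[9:12, ] <- matrix(writeBin(zi, raw(), size = 4), nrow = 4)
  rec[15, ] <- as.raw(bitwOr(1L, bitwShiftL(1L, 3)))  # return 1 of 1
  rec[16, ] <- as.raw(cls %% 256L)
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Write points or polygons as GeoJSON
#'
#' @param geoms for points: a data.frame with `x`, `y` (other columns
#'   become properties); for polygons: a named list of two-column vertex
#'   matrices, with optional `properties` data.frame (one row each).
#' @param path output `.geojson`.
#' @param type "points" or "polygons".
#' @param properties optional data.frame of per-feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geoms, path, type = c("points", "polygons"),
                          properties = NULL) {
  type <- match.arg(type)
  if (type == "points") {
    geoms <- as.data.frame(geoms)
    props <- geoms[, setdiff(names(geoms), c("x", "y")), drop = FALSE]
    feats <- lapply(seq_len(nrow(geoms)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(geoms$x[i], geoms$y[i])),
           properties = as.list(props[i, , drop = FALSE]))
    })
  } else {
    if (!is.null(properties)) properties <- as.data.frame(properties)
    feats <- lapply(seq_along(geoms), function(i) {
      ring <- geoms[[i]]
      ring <- rbind(ring, ring[1, ])      # close the ring
      list(type = "Feature",
           geometry = list(
             type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(k) ring[k, ]))),
           properties = if (is.null(properties)) {
             list(id = names(geoms)[i])
           } else as.list(properties[i, , drop = FALSE]))
    })
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' @param path a `.geojson` file written by [write_geojson()] (or any
#'   collection of Point/Polygon features).
#' @return for points: data.table of coordinates and properties; for
#'   polygons: named list of vertex matrices with a `properties`
#'   attribute.
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  stopifnot(identical(j$type, "FeatureCollection"))
  types <- vapply(j$features, function(f) f$geometry$type, character(1))
  if (all(types == "Point")) {
    rows <- lapply(j$features, function(f) {
      c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
        f$properties)
    })
    return(data.table::rbindlist(rows, fill = TRUE))
  }
  polys <- lapply(j$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring[-nrow(ring), , drop = FALSE]     # drop closing vertex
  })
  props <- data.table::rbindlist(lapply(j$features, function(f)
    as.data.frame(f$properties)), fill = TRUE)
  names(polys) <- if ("id" %in% names(props)) as.character(props$id) else
    as.character(seq_along(polys))
  attr(polys, "properties") <- props
  polys
}

#' Write a confusion matrix as CSV
#' @param cm a `confusion` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(reference = rownames(cm), unclass(cm),
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a confusion matrix from CSV
#' @param path CSV written by [write_confusion_csv()] (first column =
#'   reference class names, remaining columns = predicted classes).
#' @return a `confusion` matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- data.table::fread(path)
  m <- as.matrix(df[, -1, with = FALSE])
  rownames(m) <- df[[1]]
  dimnames(m) <- list(reference = rownames(m), predicted = colnames(m))
  as_confusion(m)
}
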