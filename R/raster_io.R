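#' Read a single-band raster
#'
#' Two on-disk formats are supported: ESRI ASCII grid (`.asc`, plain text)
#' and single-band float TIFF (`.tif`/`.tiff`) georeferenced by an ESRI
#' world file (`.tfw`) next to it. Both carry origin and cell size, so a
#' round trip through [write_raster()] preserves the grid georeferencing.
#'
#' @param path file path; format chosen by extension.
#' @return a `defol_grid`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") return(read_asc(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff_worldfile(path))
  stop("unsupported raster format: ", path)
}

#' Write a single-band raster
#'
#' @param g a `defol_grid`.
#' @param path output path (`.asc` or `.tif`).
#' @param digits significant digits for the ASCII format.
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path, digits = 7) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") return(write_asc(g, path, digits))
  if (ext %in% c("tif", "tiff")) return(write_tiff_worldfile(g, path))
  stop("unsupported raster format: ", path)
}

read_asc <- function(path) {
  hdr <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  # ASC anchors at the lower-left corner; convert to upper-left origin
  if (!is.null(hdr$xllcorner)) {
    x0 <- hdr$xllcorner; y0 <- hdr$yllcorner + nr * cs
  } else {
    x0 <- hdr$xllcenter - cs / 2; y0 <- hdr$yllcenter - cs / 2 + nr * cs
  }
  grid_create(m, c(x0, y0), cs, nodata)
}

write_asc <- function(g, path, digits = 7) {
  d <- dim(g$values)
  ext <- grid_extent(g)
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.6f", ext["xmin"]),
    sprintf("yllcorner %.6f", ext["ymin"]),
    sprintf("cellsize %.6f", g$cell_size),
    sprintf("NODATA_value %g", g$nodata))
  body <- apply(v, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

worldfile_path <- function(path) sub("\\.tiff?$", ".tfw", path,
                                     ignore.case = TRUE)

aux_path <- function(path) paste0(path, ".aux.json")

read_tiff_worldfile <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  wf <- as.numeric(readLines(worldfile_path(path)))
  stopifnot(length(wf) == 6)
  cs <- wf[1]
  # world file stores the center of the upper-left pixel
  origin <- c(wf[5] - cs / 2, wf[6] + cs / 2)
  if (file.exists(aux_path(path))) {
    aux <- jsonlite::read_json(aux_path(path))
    nas <- if (isTRUE(aux$has_na)) m >= 1 - 1e-7 else rep(FALSE, length(m))
    m <- aux$vmin + m * (aux$vmax - aux$vmin)
    m[nas] <- NA_real_
  }
  m[!is.finite(m)] <- NA_real_
  grid_create(m, origin, cs)
}

# TIFF samples must live in [0, 1]: values are affinely rescaled and the
# range stored in a JSON sidecar; NA encodes as the top of the range.
write_tiff_worldfile <- function(g, path) {
  v <- g$values
  has_na <- anyNA(v)
  vmin <- suppressWarnings(min(v, na.rm = TRUE))
  vmax <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(vmin)) { vmin <- 0; vmax <- 1 }
  # reserve the top code for NA; widen degenerate ranges
  span <- if (vmax > vmin) (vmax - vmin) / 0.99 else 1
  sv <- (v - vmin) / span
  sv[is.na(sv)] <- 1
  tiff::writeTIFF(sv, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(vmin = vmin, vmax = vmin + span,
                            has_na = has_na),
                       aux_path(path), auto_unbox = TRUE, digits = NA)
  ctr <- grid_cell_center(g, 1, 1)
  writeLines(sprintf("%.10f", c(g$cell_size, 0, 0, -g$cell_size,
                                ctr[1], ctr[2])),
             worldfile_path(path))
  invisible(path)
}
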