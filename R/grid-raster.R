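#' Lightweight georeferenced grid
#'
#' A `grid_raster` is a matrix of cell values with geographic registration:
#' lower-left corner, square cell size in decimal degrees, and a CRS tag
#' (geographic coordinates, EPSG:4326 by default). Row 1 is the northernmost
#' row, matching the on-disk order of the ESRI ASCII grid format used for
#' interchange. `NA` encodes NoData.
#'
#' @param values numeric matrix; row 1 = north.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid (°).
#' @param cellsize cell edge length in decimal degrees.
#' @param crs CRS tag carried through I/O; default `"EPSG:4326"`.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll, yll, cellsize, crs = "EPSG:4326") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(xll), is.finite(yll), cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, crs = crs),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf(
    "grid_raster: %d rows x %d cols, cellsize %g deg, xll %g, yll %g, %s\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll, x$crs))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  finite cells: %d, range [%g, %g]\n",
                length(v), min(v), max(v)))
  } else cat("  all NoData\n")
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell-centre coordinates
#'
#' Longitude/latitude of every cell centre, in cell-index order
#' (column-major over the value matrix, i.e. `as.vector(values)` order).
#'
#' @param r a `grid_raster`.
#' @return data.frame with columns `cell`, `row`, `col`, `lon`, `lat`.
#' @export
grid_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    cell = seq_len(nr * nc), row = row, col = col,
    lon = r$xll + (col - 0.5) * r$cellsize,
    lat = r$yll + (nr - row + 0.5) * r$cellsize
  )
}

#' Test that two grids share the same registration
#'
#' @param a,b `grid_raster` objects.
#' @param tol numeric tolerance on origin and cell size.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) {
    stop(sprintf(
      "%s are not co-registered (dims %sx%s vs %sx%s, origin/cellsize differ); no silent resampling is performed",
      what, nrow(a$values), ncol(a$values), nrow(b$values), ncol(b$values)),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Look up the cell index containing a coordinate
#'
#' @param r a `grid_raster`.
#' @param lon,lat coordinate vectors (°).
#' @return integer cell indices (`NA` outside the grid extent).
#' @export
cell_from_xy <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((lon - r$xll) / r$cellsize) + 1L
  row <- nr - floor((lat - r$yll) / r$cellsize)
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- rep(NA_integer_, length(lon))
  out[ok] <- (col[ok] - 1L) * nr + row[ok]
  out
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south.
#'
#' @param path file path.
#' @param crs CRS tag to attach (the .asc format itself carries none).
#' @return a `grid_raster`.
#' @export
read_asc <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `grid_raster`.
#' @param path output file path.
#' @param nodata numeric NoData sentinel written in place of `NA`.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  m <- r$values
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(r$xll, digits = 15)),
    paste("yllcorner", format(r$yll, digits = 15)),
    paste("cellsize", format(r$cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  apply(m, 1L, function(row)
    writeLines(paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
                     collapse = " "), con))
  invisible(path)
}
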