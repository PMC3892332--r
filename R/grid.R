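#' Lon/lat raster grid
#'
#' `bam_grid()` builds the package's raster container: a matrix of cell values
#' on a regular longitude/latitude lattice with square cells.  Row 1 is the
#' northernmost row; column 1 the westernmost.  The extent gives the *outer
#' cell edges*, so `ncol(values) == (lon_max - lon_min) / resolution` and
#' likewise for rows.  Cells excluded from analysis (sea, nodata) are `FALSE`
#' in `mask` and `NA` in `values`.
#'
#' The `kind` tag documents (and enforces) what the values mean:
#' `"continuous"` for raw predictors, `"probability"` for suitabilities in
#' \[0, 1\], `"binary"` for presence/absence maps in \{0, 1\}.
#'
#' @param values numeric matrix (rows x cols), row 1 = north.  `NA` marks
#'   invalid cells if `mask` is not given.
#' @param extent numeric length-4: `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees, outer cell edges.
#' @param resolution cell size in degrees (square cells).
#' @param mask logical matrix of the same shape; `FALSE` = invalid.  Defaults
#'   to `!is.na(values)`.
#' @param kind one of `"continuous"`, `"probability"`, `"binary"`.
#' @return an object of class `bam_grid`.
#' @export
bam_grid <- function(values, extent, resolution,
                     mask = NULL, kind = c("continuous", "probability", "binary")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  extent <- as.numeric(extent)
  if (length(extent) != 4L)
    stop("extent must be c(lon_min, lon_max, lat_min, lat_max)")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number")
  nr <- as.integer(round((extent[4L] - extent[3L]) / resolution))
  nc <- as.integer(round((extent[2L] - extent[1L]) / resolution))
  if (nr != nrow(values) || nc != ncol(values))
    stop(sprintf("extent/resolution imply %d x %d cells but values is %d x %d",
                 nr, nc, nrow(values), ncol(values)))
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("mask must be a logical matrix with the same shape as values")
  mask <- mask & !is.na(values)
  values[!mask] <- NA_real_
  v <- values[mask]
  if (kind == "probability" && length(v) && (min(v) < 0 || max(v) > 1))
    stop("probability grid has valid values outside [0, 1]")
  if (kind == "binary" && length(v) && !all(v %in% c(0, 1)))
    stop("binary grid has valid values outside {0, 1}")
  structure(
    list(values = values, extent = extent, resolution = resolution,
         mask = mask, kind = kind),
    class = "bam_grid")
}

#' @export
print.bam_grid <- function(x, ...) {
  cat(sprintf("<bam_grid> %d x %d cells, res %.6g deg, kind '%s'\n",
              nrow(x$values), ncol(x$values), x$resolution, x$kind))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]; %d valid / %d cells\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @rdname bam_grid
#' @param x object to test.
#' @export
is_bam_grid <- function(x) inherits(x, "bam_grid")

# Longitudes of column centers / latitudes of row centers (row 1 = north).
grid_lon_centers <- function(g) g$extent[1L] + (seq_len(ncol(g$values)) - 0.5) * g$resolution
grid_lat_centers <- function(g) g$extent[4L] - (seq_len(nrow(g$values)) - 0.5) * g$resolution

#' Locate points on a grid's lattice
#'
#' Maps lon/lat points to (row, col) indices under the half-open cell
#' convention: a cell owns `[edge, edge + resolution)` on both axes, so a
#' point exactly on a shared edge belongs to the cell to its east/north-side
#' lower edge (lower/left inclusive).  Points outside the extent get `NA`.
#'
#' @param grid a [bam_grid].
#' @param lon,lat numeric vectors of equal length.
#' @return integer matrix with columns `row`, `col` (`NA` when outside).
#' @keywords internal
cell_index <- function(grid, lon, lat) {
  res <- grid$resolution
  eps <- res * 1e-9
  ic <- floor((lon - grid$extent[1L]) / res + eps)
  ir_from_s <- floor((lat - grid$extent[3L]) / res + eps)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ok <- is.finite(lon) & is.finite(lat) & ic >= 0 & ic < nc & ir_from_s >= 0 & ir_from_s < nr
  row <- ifelse(ok, nr - ir_from_s, NA_integer_)
  col <- ifelse(ok, ic + 1L, NA_integer_)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Crop a grid to a lon/lat window
#'
#' The window is snapped *outward* to the grid's cell lattice, then
#' intersected with the grid extent; the result is an exact sub-array of the
#' input (no resampling).  The default projection window used throughout the
#' package is Europe, 12W-60E and 30N-75N.
#'
#' @param grid a [bam_grid].
#' @param window numeric length-4 `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return the cropped [bam_grid].
#' @export
crop_grid <- function(grid, window) {
  window <- as.numeric(window)
  if (length(window) != 4L) stop("window must be length 4")
  if (window[1L] >= window[2L] || window[3L] >= window[4L])
    stop("window must have positive lon and lat span")
  e <- grid$extent; res <- grid$resolution
  eps <- res * 1e-9
  if (window[2L] <= e[1L] || window[1L] >= e[2L] ||
      window[4L] <= e[3L] || window[3L] >= e[4L])
    stop("crop window is disjoint from the grid extent")
  # snap outward to the lattice, then clamp to the extent
  c0 <- max(0L, as.integer(floor((window[1L] - e[1L]) / res + eps)))
  c1 <- min(ncol(grid$values), as.integer(ceiling((window[2L] - e[1L]) / res - eps)))
  r0s <- max(0L, as.integer(floor((window[3L] - e[3L]) / res + eps)))      # from south
  r1s <- min(nrow(grid$values), as.integer(ceiling((window[4L] - e[3L]) / res - eps)))
  nr <- nrow(grid$values)
  rows <- (nr - r1s + 1L):(nr - r0s)   # row 1 = north
  cols <- (c0 + 1L):c1
  new_extent <- c(e[1L] + c0 * res, e[1L] + c1 * res,
                  e[3L] + r0s * res, e[3L] + r1s * res)
  bam_grid(grid$values[rows, cols, drop = FALSE], new_extent, res,
           mask = grid$mask[rows, cols, drop = FALSE], kind = grid$kind)
}

#' Read a raster grid from file
#'
#' Supports the ESRI ASCII grid format (`ascii_grid`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`; keys case-insensitive) followed by
#' `nrows` whitespace-separated data rows, first row = northernmost.
#' GeoTIFF is not supported by this build and raises an error.
#'
#' @param path file path.
#' @param format_id `"ascii_grid"` (or `"geotiff"`, unsupported).
#' @param kind value-kind tag for the returned grid, see [bam_grid].
#' @return a [bam_grid]; nodata cells are invalid.
#' @export
read_grid <- function(path, format_id = c("ascii_grid", "geotiff"),
                      kind = "continuous") {
  format_id <- match.arg(format_id)
  if (format_id == "geotiff")
    stop("GeoTIFF input is not supported; supply an ESRI ASCII grid")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "xllcenter", "yllcenter", "cellsize", "nodata_value")))
      break
    if (length(parts) != 2L)
      stop("malformed header line for field '", key, "'")
    hdr[[key]] <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(hdr[[key]]))
      stop("non-numeric value for header field '", key, "'")
    i <- i + 1L
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]])) stop("missing header field '", req, "'")
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("missing header field 'xllcorner'")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("missing header field 'yllcorner'")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  res <- hdr$cellsize
  if (res <= 0) stop("non-positive value for header field 'cellsize'")
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - res / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - res / 2
  data_lines <- lines[i:length(lines)]
  if (length(data_lines) != nr)
    stop(sprintf("header field 'nrows' declares %d rows but file has %d data rows",
                 nr, length(data_lines)))
  rows <- lapply(data_lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(v)) stop("non-numeric data value in grid body")
    v
  })
  lens <- lengths(rows)
  if (any(lens != nc))
    stop(sprintf("header field 'ncols' declares %d columns but row %d holds %d values",
                 nc, which(lens != nc)[1L], lens[lens != nc][1L]))
  values <- do.call(rbind, rows)
  if (!is.null(hdr$nodata_value))
    values[values == hdr$nodata_value] <- NA_real_
  extent <- c(xll, xll + nc * res, yll, yll + nr * res)
  bam_grid(values, extent, res, kind = kind)
}

#' Write a raster grid to file
#'
#' Writes ESRI ASCII grid format; invalid cells become the nodata sentinel.
#' `read_grid()` on the written file reproduces values, extent, resolution,
#' and mask.
#'
#' @param grid a [bam_grid].
#' @param path output path.
#' @param format_id `"ascii_grid"` (or `"geotiff"`, unsupported).
#' @param nodata sentinel for invalid cells (must not collide with data).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format_id = c("ascii_grid", "geotiff"),
                       nodata = -9999) {
  format_id <- match.arg(format_id)
  if (format_id == "geotiff")
    stop("GeoTIFF output is not supported; use format_id = 'ascii_grid'")
  v <- grid$values
  if (any(v[grid$mask] == nodata, na.rm = TRUE))
    stop("nodata sentinel collides with a valid data value")
  v[!grid$mask] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.12g", grid$extent[1L]),
           sprintf("yllcorner %.12g", grid$extent[3L]),
           sprintf("cellsize %.12g", grid$resolution),
           sprintf("NODATA_value %.12g", nodata))
  body <- apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
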