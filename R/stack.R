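#' Stack of aligned environmental predictor grids
#'
#' A `predictor_stack` is an ordered, named list of [bam_grid] layers sharing
#' extent, resolution and shape — the covariates of every niche model in the
#' package.  The default layer names follow the four bioclimatic variables
#' used throughout: minimum temperature of the coldest month (`MinT`),
#' maximum temperature of the warmest month (`MaxT`), annual precipitation
#' (`AnPrec`) and precipitation seasonality (`PrecSeas`).  A cell is valid in
#' the stack only if it is valid in *every* layer.
#'
#' @param layers named list of [bam_grid] objects.
#' @return an object of class `predictor_stack` with elements `layers`
#'   (each layer's mask reduced to the joint mask) and `mask`.
#' @export
predictor_stack <- function(layers) {
  if (!length(layers)) stop("at least one layer required")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  if (anyDuplicated(names(layers))) stop("layer names must be unique")
  ref <- layers[[1L]]
  for (nm in names(layers)) {
    g <- layers[[nm]]
    if (!is_bam_grid(g)) stop("layer '", nm, "' is not a bam_grid")
    if (!isTRUE(all.equal(g$extent, ref$extent)) ||
        !isTRUE(all.equal(g$resolution, ref$resolution)) ||
        !identical(dim(g$values), dim(ref$values)))
      stop("layer '", nm, "' is not aligned with layer '", names(layers)[1L], "'")
  }
  mask <- Reduce(`&`, lapply(layers, `[[`, "mask"))
  layers <- lapply(layers, function(g)
    bam_grid(g$values, g$extent, g$resolution, mask = mask, kind = g$kind))
  structure(list(layers = layers, mask = mask,
                 extent = ref$extent, resolution = ref$resolution),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers (%s), %d x %d cells, res %.6g deg\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$mask), ncol(x$mask), x$resolution))
  invisible(x)
}

#' @rdname predictor_stack
#' @param x object to test.
#' @export
is_predictor_stack <- function(x) inherits(x, "predictor_stack")

#' Crop every layer of a stack to a window
#'
#' @param stack a [predictor_stack].
#' @param window lon/lat window as in [crop_grid].
#' @return a cropped [predictor_stack].
#' @export
crop_stack <- function(stack, window) {
  predictor_stack(lapply(stack$layers, crop_grid, window = window))
}

#' Extract predictor values at points
#'
#' Looks up, for each lon/lat point, the values of all stack layers in the
#' cell containing the point (half-open cell convention, lower/left edge
#' inclusive).  Failures are reported through the validity flags, never as
#' errors: a point outside the extent, or on a cell invalid in any layer,
#' gets `valid = FALSE` and `NA` predictor values.
#'
#' @param stack a [predictor_stack].
#' @param lon,lat numeric point coordinates (equal length).
#' @return list with `values` (n x p matrix, columns named by layer) and
#'   `valid` (logical length n).
#' @export
extract_values <- function(stack, lon, lat) {
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  g1 <- stack$layers[[1L]]
  idx <- cell_index(g1, lon, lat)
  n <- length(lon); p <- length(stack$layers)
  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, names(stack$layers)))
  inside <- !is.na(idx[, "row"])
  if (any(inside)) {
    flat <- (idx[inside, "col"] - 1L) * nrow(g1$values) + idx[inside, "row"]
    for (j in seq_len(p)) vals[inside, j] <- stack$layers[[j]]$values[flat]
    valid_cell <- stack$mask[flat]
  }
  valid <- logical(n)
  if (any(inside)) valid[inside] <- valid_cell
  vals[!valid, ] <- NA_real_
  list(values = vals, valid = valid)
}

# Data frame of all valid cells: lon, lat, and one column per predictor.
# Used for raster projection and pseudo-absence sampling.
stack_cell_table <- function(stack) {
  g1 <- stack$layers[[1L]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  keep <- which(stack$mask)  # column-major flat indices
  row <- ((keep - 1L) %% nr) + 1L
  col <- ((keep - 1L) %/% nr) + 1L
  lon <- g1$extent[1L] + (col - 0.5) * g1$resolution
  lat <- g1$extent[4L] - (row - 0.5) * g1$resolution
  out <- data.frame(cell = keep, row = row, col = col, lon = lon, lat = lat)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[keep]
  out
}
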