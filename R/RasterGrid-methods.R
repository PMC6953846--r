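#' @include AllGenerics.R
NULL

#' Construct a RasterGrid
#'
#' @param values a matrix (single band) or 3-D array `[row, col, band]`.
#' @param bandNames character band names; defaults to `"layer1"`, ... when
#'   `values` carries none.
#' @param xmin,ymax map coordinates of the top-left corner.
#' @param pixelSize pixel edge length in metres.
#' @param crs CRS identifier string.
#' @param nodata sentinel written to file for `NA` cells.
#' @return a [RasterGrid-class].
#' @examples
#' g <- RasterGrid(matrix(runif(100), 10), bandNames = "B5")
#' dim(g)
#' @export
RasterGrid <- function(values, bandNames = NULL, xmin = 0, ymax = NULL,
                       pixelSize = 30, crs = "local", nodata = -9999) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L)
    stop("values must be a matrix or 3-D array")
  nb <- dim(values)[3L]
  if (is.null(bandNames)) bandNames <- dimnames(values)[[3L]]
  if (is.null(bandNames)) bandNames <- paste0("layer", seq_len(nb))
  if (length(bandNames) != nb) stop("one name per band required")
  dimnames(values) <- list(NULL, NULL, bandNames)
  if (is.null(ymax)) ymax <- dim(values)[1L] * pixelSize
  new("RasterGrid", values = values, xmin = xmin, ymax = ymax,
      pixelSize = pixelSize, crs = crs, nodata = nodata)
}

#' @rdname gridValues
setMethod("gridValues", "RasterGrid", function(x, band = NULL) {
  if (is.null(band)) return(x@values)
  x@values[, , band]
})

#' @rdname gridValues
setMethod("bandNames", "RasterGrid", function(x) dimnames(x@values)[[3L]])

#' @rdname gridValues
setMethod("pixelSize", "RasterGrid", function(x) x@pixelSize)

#' @rdname gridValues
setMethod("gridCRS", "RasterGrid", function(x) x@crs)

#' @rdname gridValues
setMethod("nodataValue", "RasterGrid", function(x) x@nodata)

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("RasterGrid: %d x %d pixels, %d band(s) [%s]\n", d[1], d[2],
              d[3], paste(bandNames(object), collapse = ", ")))
  cat(sprintf("  pixel %g m, origin (%g, %g), crs '%s'\n", object@pixelSize,
              object@xmin, object@ymax, object@crs))
  cat(sprintf("  NA cells: %d / %d\n", sum(is.na(object@values)),
              length(object@values)))
})

# ---- internal grid helpers ---------------------------------------------

## identical shape + georeference; names the offender in errors
stopifnotSameGrid <- function(a, b, what = "rasters") {
  da <- dim(a@values)[1:2]; db <- dim(b@values)[1:2]
  if (!identical(da, db))
    stop(sprintf("%s differ in shape: %dx%d vs %dx%d", what,
                 da[1], da[2], db[1], db[2]))
  if (!identical(a@crs, b@crs))
    stop(sprintf("%s differ in CRS: '%s' vs '%s'", what, a@crs, b@crs))
  if (abs(a@xmin - b@xmin) > 1e-6 || abs(a@ymax - b@ymax) > 1e-6 ||
      abs(a@pixelSize - b@pixelSize) > 1e-9)
    stop(sprintf("%s are not co-registered", what))
  invisible(TRUE)
}

## single-band grid carrying the georeference of a template
gridLike <- function(template, values, bandName = "layer1") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  dimnames(values) <- list(NULL, NULL, bandName)
  new("RasterGrid", values = values, xmin = template@xmin,
      ymax = template@ymax, pixelSize = template@pixelSize,
      crs = template@crs, nodata = template@nodata)
}

## pixel-center map coordinates for (row, col) matrices/vectors
pixelCenters <- function(grid, row, col) {
  cbind(x = grid@xmin + (col - 0.5) * grid@pixelSize,
        y = grid@ymax - (row - 0.5) * grid@pixelSize)
}
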