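#' @include AllClasses.R
NULL

#' Accessors for raster and map objects
#'
#' `gridValues` returns the value array (or a single band as a matrix),
#' `bandNames` the band names, `pixelSize` the pixel edge length in metres,
#' `gridCRS` the CRS identifier, and `nodataValue` the file-level sentinel.
#'
#' @param x a [RasterGrid-class] or an object wrapping one.
#' @param band optional band name or index; if given, a matrix is returned.
#' @return see details above.
#' @aliases gridValues bandNames pixelSize gridCRS nodataValue
#' @export
setGeneric("gridValues", function(x, band = NULL) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname gridValues
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname gridValues
#' @export
setGeneric("gridCRS", function(x) standardGeneric("gridCRS"))

#' @rdname gridValues
#' @export
setGeneric("nodataValue", function(x) standardGeneric("nodataValue"))

#' Gap mask of a composite
#'
#' Logical matrix flagging pixels with zero valid observations.
#' @param x a [Composite-class].
#' @return logical matrix.
#' @export
setGeneric("gapMask", function(x) standardGeneric("gapMask"))

#' Legend accessors
#'
#' `legendCodes`/`legendNames` return the class codes and names;
#' `legendColors` the hex colors named by code.
#' @param x a [ClassLegend-class] or [LandCoverMap-class].
#' @aliases legendCodes legendNames legendColors
#' @export
setGeneric("legendCodes", function(x) standardGeneric("legendCodes"))

#' @rdname legendCodes
#' @export
setGeneric("legendNames", function(x) standardGeneric("legendNames"))

#' @rdname legendCodes
#' @export
setGeneric("legendColors", function(x) standardGeneric("legendColors"))
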