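#' @include compositing.R
NULL

# Index formulas over composite bands. Normalized differences are
# (A - B)/(A + B); ratio indices divide directly. A near-zero denominator
# (|d| < eps) yields NA rather than +/-Inf so that threshold comparisons
# stay well-defined.
INDEX_FORMULAS <- list(
  NDMI  = function(B) (B$B7 - B$B3) / (B$B7 + B$B3),
  MNDWI = function(B) (B$B3 - B$B6) / (B$B3 + B$B6),
  NDBI  = function(B) (B$B6 - B$B5) / (B$B6 + B$B5),
  NDII  = function(B) (B$B3 - B$B10) / (B$B3 + B$B10),
  NDBaI = function(B) (B$B6 - B$B10) / (B$B6 + B$B10),
  BI    = function(B) (B$B6 - B$B7) / (B$B6 + B$B7),
  UI    = function(B) (B$B7 - B$B5) / (B$B7 + B$B5),
  NDVI  = function(B) (B$B5 - B$B4) / (B$B5 + B$B4),
  GCVI  = function(B) (B$B5 / B$B3) - 1,
  SR    = function(B) B$B5 / B$B4,
  R75   = function(B) B$B7 / B$B5,
  R65   = function(B) B$B6 / B$B5,
  R34   = function(B) B$B3 / B$B4)

INDEX_DENOMS <- list(
  NDMI = c("B7", "B3"), MNDWI = c("B3", "B6"), NDBI = c("B6", "B5"),
  NDII = c("B3", "B10"), NDBaI = c("B6", "B10"), BI = c("B6", "B7"),
  UI = c("B7", "B5"), NDVI = c("B5", "B4"), GCVI = "B3", SR = "B4",
  R75 = "B5", R65 = "B5", R34 = "B4")

denomOf <- function(B, name) {
  dn <- INDEX_DENOMS[[name]]
  if (length(dn) == 2L) B[[dn[1]]] + B[[dn[2]]] else B[[dn]]
}

#' Compute one spectral index from a composite
#'
#' Evaluates the index formula exactly as printed in the predictor table
#' (e.g. MNDWI = (B3 - B6)/(B3 + B6), NDVI = (B5 - B4)/(B5 + B4),
#' GCVI = B5/B3 - 1). Pixels where the denominator magnitude is below `eps`,
#' or where an input band is missing, are NA.
#'
#' @param composite a [Composite-class].
#' @param name one of NDMI, MNDWI, NDBI, NDII, NDBaI, BI, UI, NDVI, GCVI,
#'   SR, R75, R65, R34.
#' @param eps denominator tolerance (default 1e-10).
#' @return single-band [RasterGrid-class] named after the index.
#' @export
computeIndex <- function(composite, name, eps = 1e-10) {
  if (!name %in% names(INDEX_FORMULAS))
    stop(sprintf("unknown index '%s'", name))
  B <- lapply(bandNames(composite@bands),
              function(b) gridValues(composite@bands, b))
  names(B) <- bandNames(composite@bands)
  need <- setdiff(unique(c(INDEX_DENOMS[[name]],
                           switch(name, GCVI = "B5", SR = "B5", R75 = "B7",
                                  R65 = "B6", R34 = "B3", character()))),
                  names(B))
  if (length(need))
    stop(sprintf("index %s needs missing band(s): %s", name,
                 paste(need, collapse = ", ")))
  v <- INDEX_FORMULAS[[name]](B)
  v[abs(denomOf(B, name)) < eps] <- NA
  gridLike(composite@bands, v, name)
}

#' Compute a stack of spectral indices
#'
#' Batch of [computeIndex()]; duplicate names collapse to one layer with a
#' warning; gap pixels of the composite are NA in every layer.
#'
#' @param composite a [Composite-class].
#' @param names index names (default: all 13).
#' @param eps denominator tolerance.
#' @return an [IndexStack-class] (a [RasterGrid-class] of index layers).
#' @export
computeIndexStack <- function(composite, names = KNOWN_INDICES,
                              eps = 1e-10) {
  if (anyDuplicated(names)) {
    warning("duplicate index names collapsed")
    names <- unique(names)
  }
  layers <- lapply(names, function(n) gridValues(computeIndex(composite, n, eps), 1L))
  arr <- array(unlist(layers), c(dim(layers[[1L]]), length(layers)),
               dimnames = list(NULL, NULL, names))
  b <- composite@bands
  new("IndexStack", values = arr, xmin = b@xmin, ymax = b@ymax,
      pixelSize = b@pixelSize, crs = b@crs, nodata = b@nodata,
      provenance = "composite")
}

## fetch a named layer (band or index) as a matrix
lookupLayer <- function(name, composite, indexStack = NULL) {
  if (name %in% bandNames(composite@bands))
    return(gridValues(composite@bands, name))
  if (!is.null(indexStack) && name %in% bandNames(indexStack))
    return(gridValues(indexStack, name))
  stop(sprintf("layer '%s' not found among bands or computed indices", name))
}
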