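#' @import methods
NULL

#' RasterGrid: a georeferenced multi-band raster
#'
#' The package's raster container. Values are stored as a 3-D array
#' (row, col, band) with band names on the third dimension; missing
#' observations are `NA` internally (a file-level nodata sentinel is mapped to
#' `NA` on read and back on write). Georeferencing is north-up, pixel-center:
#' the center of pixel (r, c) sits at `x = xmin + (c - 0.5) * pixelSize`,
#' `y = ymax - (r - 0.5) * pixelSize`. A single projected CRS per run is
#' assumed; inputs must be co-registered.
#'
#' @slot values numeric 3-D array `[nrow, ncol, nband]`.
#' @slot xmin,ymax numeric map coordinates of the grid's top-left corner.
#' @slot pixelSize numeric pixel edge length in metres (default 30).
#' @slot crs character CRS identifier (free-form, compared verbatim).
#' @slot nodata numeric sentinel used when writing to file.
#' @export
setClass("RasterGrid",
  representation(values = "array", xmin = "numeric", ymax = "numeric",
                 pixelSize = "numeric", crs = "character",
                 nodata = "numeric"),
  prototype(xmin = 0, ymax = 0, pixelSize = 30, crs = "local", nodata = -9999))

setValidity("RasterGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-D array [row, col, band]")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (length(object@crs) != 1L) return("crs must be a single string")
  bn <- dimnames(v)[[3L]]
  if (is.null(bn) || anyDuplicated(bn))
    return("bands must carry unique names")
  TRUE
})

#' VectorLayer: points, lines or polygons with attributes
#'
#' Geometries are stored as a list of two-column coordinate matrices (x, y) in
#' the working CRS. Polygons are closed rings (first vertex repeated last is
#' accepted but not required); multi-part features are separate list entries
#' sharing an attribute row.
#'
#' @slot geometries list of numeric matrices with columns x, y.
#' @slot geomType one of `"point"`, `"line"`, `"polygon"`.
#' @slot kind semantic role, e.g. `"settlements"`, `"concessions"`,
#'   `"shoreline"`, `"forest_extent"`, `"training_polygons"`.
#' @slot attributes data.frame with one row per geometry.
#' @slot crs character CRS identifier.
#' @export
setClass("VectorLayer",
  representation(geometries = "list", geomType = "character",
                 kind = "character", attributes = "data.frame",
                 crs = "character"),
  prototype(geomType = "point", kind = "generic", crs = "local"))

setValidity("VectorLayer", function(object) {
  if (!object@geomType %in% c("point", "line", "polygon"))
    return("geomType must be point, line or polygon")
  if (length(object@geometries) &&
      !all(vapply(object@geometries,
                  function(g) is.matrix(g) && ncol(g) == 2L && nrow(g) >= 1L,
                  logical(1))))
    return("each geometry must be a two-column coordinate matrix")
  if (object@geomType == "polygon" &&
      any(vapply(object@geometries, nrow, integer(1)) < 3L))
    return("polygon rings need at least 3 vertices")
  if (nrow(object@attributes) &&
      nrow(object@attributes) != length(object@geometries))
    return("attributes must have one row per geometry")
  TRUE
})

#' ClassLegend: the map's class dictionary
#'
#' Ordered set of land-cover classes. Code 0 is reserved for
#' unclassified/other; class codes are small positive integers. The entry
#' order is the legend (reporting) order; the classification order is a
#' separate field of the pipeline configuration.
#'
#' @slot entries data.frame with columns `code` (integer >= 1), `name`,
#'   `color` (hex), `applicability` (free-form country tag).
#' @export
setClass("ClassLegend",
  representation(entries = "data.frame"))

setValidity("ClassLegend", function(object) {
  e <- object@entries
  need <- c("code", "name", "color", "applicability")
  if (!all(need %in% names(e)))
    return(paste("legend entries need columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$code)) return("legend codes must be unique")
  if (anyDuplicated(e$name)) return("legend names must be unique")
  if (any(e$code < 1L)) return("class codes must be >= 1 (0 is reserved)")
  TRUE
})

#' SceneStack: one acquisition
#'
#' A multiband reflectance raster plus a QA bit-flag raster sharing its grid,
#' an acquisition date, and a season tag used by windowed compositing.
#'
#' @slot bands [RasterGrid-class] of reflectance bands (B2..B7, B10).
#' @slot qa [RasterGrid-class] single-band integer bit flags.
#' @slot date `Date` of acquisition.
#' @slot season `"dry"` or `"rainy"`.
#' @export
setClass("SceneStack",
  representation(bands = "RasterGrid", qa = "RasterGrid", date = "Date",
                 season = "character"))

setValidity("SceneStack", function(object) {
  if (!identical(dim(object@bands@values)[1:2], dim(object@qa@values)[1:2]))
    return("bands and qa must share the grid shape")
  if (!object@season %in% c("dry", "rainy"))
    return("season must be 'dry' or 'rainy'")
  TRUE
})

#' Composite: gap-flagged median composite
#'
#' Per-band, per-pixel median over the valid (cloud-free, non-fill)
#' observations of a scene collection, together with the per-pixel count of
#' contributing observations. Pixels with zero valid observations are gaps:
#' `NA` in every band, flagged by `gapMask()`.
#'
#' @slot bands [RasterGrid-class] composited bands.
#' @slot validCount [RasterGrid-class] single band of observation counts.
#' @export
setClass("Composite",
  representation(bands = "RasterGrid", validCount = "RasterGrid"))

setValidity("Composite", function(object) {
  if (!identical(dim(object@bands@values)[1:2],
                 dim(object@validCount@values)[1:2]))
    return("bands and validCount must share the grid shape")
  cnt <- object@validCount@values[, , 1L]
  gap <- cnt == 0L
  anyband <- apply(!is.na(object@bands@values), c(1, 2), any)
  if (any(gap & anyband, na.rm = TRUE))
    return("gap pixels (validCount == 0) must be NA in all bands")
  TRUE
})

#' IndexStack: named spectral-index layers
#'
#' A [RasterGrid-class] whose bands are spectral indices computed from a
#' composite, carrying the provenance of its source.
#'
#' @slot provenance character id of the source composite.
#' @export
setClass("IndexStack", contains = "RasterGrid",
  representation(provenance = "character"),
  prototype(provenance = "unknown"))

#' MaskRule: one pre-classification masking constraint
#'
#' Spectral rules (`kind = "spectral"`) compare a band or index layer against
#' a threshold with a strict `>` or `<` comparator, exactly as printed
#' threshold tables use them. Spatial rules (`kind = "spatial"`) encode
#' ancillary constraints: `within_buffer` (points/lines layer plus radius in
#' m), `within_polygons`, `elevation_below` (DEM cap in m),
#' `slope_below` (verification, cap in degrees) and `after_class_removed`
#' (ordering dependency on a previously mapped class). Rules in a class
#' specification combine by logical AND.
#'
#' @slot kind `"spectral"` or `"spatial"`.
#' @slot layer band/index name (spectral) or ancillary layer name (spatial).
#' @slot comparator `">"` or `"<"` (spectral only).
#' @slot threshold numeric threshold (spectral only).
#' @slot constraint spatial constraint type (spatial only).
#' @slot params list of constraint parameters (e.g. `radius`, `cap`, `class`).
#' @export
setClass("MaskRule",
  representation(kind = "character", layer = "character",
                 comparator = "character", threshold = "numeric",
                 constraint = "character", params = "list"),
  prototype(kind = "spectral", layer = NA_character_, comparator = ">",
            threshold = NA_real_, constraint = NA_character_,
            params = list()))

setValidity("MaskRule", function(object) {
  if (!object@kind %in% c("spectral", "spatial"))
    return("kind must be 'spectral' or 'spatial'")
  if (object@kind == "spectral") {
    if (!object@comparator %in% c(">", "<"))
      return("spectral comparator must be '>' or '<'")
    if (is.na(object@threshold)) return("spectral rule needs a threshold")
    if (is.na(object@layer)) return("spectral rule needs a layer name")
  } else {
    ok <- c("within_buffer", "within_polygons", "elevation_below",
            "slope_below", "after_class_removed")
    if (!object@constraint %in% ok)
      return(paste("unknown spatial constraint; use one of:",
                   paste(ok, collapse = ", ")))
    if (object@constraint == "within_buffer" &&
        (is.null(object@params$radius) || object@params$radius <= 0))
      return("within_buffer needs params$radius > 0 (metres)")
  }
  TRUE
})

#' ClassSpec: everything needed to map one class
#'
#' @slot code legend code of the class.
#' @slot name class name.
#' @slot phase1 list of spectral [MaskRule-class] objects (Masking Phase I).
#' @slot phase2 list of spatial [MaskRule-class] objects (Masking Phase II).
#' @slot predictors character layer names fed to the class's random forest.
#' @slot verify list of [MaskRule-class] verification rules applied after
#'   classification (e.g. a slope cap for water).
#' @export
setClass("ClassSpec",
  representation(code = "integer", name = "character", phase1 = "list",
                 phase2 = "list", predictors = "character", verify = "list"),
  prototype(phase1 = list(), phase2 = list(), verify = list()))

#' PipelineConfig: resolved configuration of one mapping run
#'
#' @slot country `"liberia"`, `"gabon"` or `"custom"`.
#' @slot legend [ClassLegend-class].
#' @slot specs named list of [ClassSpec-class], one per legend class.
#' @slot order integer class codes in classification order.
#' @slot floodCodes integer codes assigned from the SAR flood map (named
#'   `seasonal`, `permanent`), empty when the profile has none.
#' @slot trees number of random-forest trees (default 100).
#' @slot nPerClassValidation stratified validation samples per class (50).
#' @slot seed integer random seed recorded in outputs.
#' @slot qaDialect named list of QA bit positions (`cloud`, `shadow`, `fill`).
#' @slot window list describing the compositing window (`style`
#'   `"seasonal"`/`"annual"`, `centerYear`, `season`).
#' @slot params named list of tunable scalars: `settlementBufferM`,
#'   `shoreBufferM`, `slopeCapDeg`, `demCapM`, `floodDemCapM`,
#'   `minTrainPerLabel`, `denomEps`.
#' @export
setClass("PipelineConfig",
  representation(country = "character", legend = "ClassLegend",
                 specs = "list", order = "integer", floodCodes = "integer",
                 trees = "integer", nPerClassValidation = "integer",
                 seed = "integer", qaDialect = "list", window = "list",
                 params = "list"),
  prototype(trees = 100L, nPerClassValidation = 50L, seed = 1L,
            floodCodes = integer(),
            qaDialect = list(cloud = 0L, shadow = 1L, fill = 2L)))

setValidity("PipelineConfig", function(object) {
  codes <- object@legend@entries$code
  if (!all(names(object@specs) %in% object@legend@entries$name))
    return("every spec must be named after a legend class")
  speccodes <- vapply(object@specs, function(s) s@code, integer(1))
  if (!all(codes %in% c(speccodes, object@floodCodes)))
    return("every legend class needs a ClassSpec (or a flood code)")
  if (!all(object@order %in% codes))
    return("classification order refers to unknown class codes")
  if (object@trees < 1L) return("trees must be >= 1")
  TRUE
})

#' LandCoverMap: the pipeline's product
#'
#' Integer-coded single-band raster with its legend and per-class provenance.
#' Code 0 is unclassified; `NA` marks gaps/nodata.
#'
#' @slot grid [RasterGrid-class] single integer band of class codes.
#' @slot legend [ClassLegend-class].
#' @slot provenance list of per-class records (iteration, training size,
#'   candidate count) plus run metadata such as the seed.
#' @export
setClass("LandCoverMap",
  representation(grid = "RasterGrid", legend = "ClassLegend",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("LandCoverMap", function(object) {
  v <- object@grid@values
  if (dim(v)[3L] != 1L) return("a land-cover map has exactly one band")
  codes <- c(0L, object@legend@entries$code)
  bad <- setdiff(unique(as.vector(v[!is.na(v)])), codes)
  if (length(bad))
    return(paste("map contains codes outside the legend:",
                 paste(bad, collapse = ", ")))
  TRUE
})

#' FloodMap: permanent / seasonal flooded-forest raster
#'
#' Codes: 0 = not flooded, 1 = seasonally flooded (detected only in the rainy
#' season), 2 = permanently flooded (detected in both seasons). Dry-only
#' detections are counted as anomalies and left not flooded.
#'
#' @slot grid [RasterGrid-class] single-band code raster.
#' @slot anomalies integer count of dry-only detections.
#' @export
setClass("FloodMap",
  representation(grid = "RasterGrid", anomalies = "integer"),
  prototype(anomalies = 0L))

setValidity("FloodMap", function(object) {
  v <- object@grid@values
  bad <- setdiff(unique(as.vector(v[!is.na(v)])), c(0L, 1L, 2L))
  if (length(bad)) return("flood map codes must be 0, 1 or 2")
  TRUE
})

#' ErrorMatrix: confusion counts between reference and map labels
#'
#' A square count matrix indexed reference class (rows) by map class
#' (columns). All accuracy statistics derive from it.
#'
#' @slot counts integer matrix with identical row/column class-name dimnames.
#' @export
setClass("ErrorMatrix", representation(counts = "matrix"))

setValidity("ErrorMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("error matrix must be square")
  if (!identical(rownames(m), colnames(m)))
    return("row and column class labels must match")
  if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
  TRUE
})

#' SpectralLibrary: per-class band signatures for the scene generator
#'
#' @slot means numeric matrix class x band of mean reflectance in [0, 1].
#' @slot sds numeric matrix class x band of within-class standard deviations.
#' @slot seasonalOffset numeric matrix class x band added in rainy-season
#'   scenes (dry season is the baseline).
#' @export
setClass("SpectralLibrary",
  representation(means = "matrix", sds = "matrix",
                 seasonalOffset = "matrix"))

setValidity("SpectralLibrary", function(object) {
  if (any(object@means < 0 | object@means > 1))
    return("means must lie in [0, 1]")
  if (any(object@sds < 0)) return("sds must be >= 0")
  if (!identical(dim(object@means), dim(object@sds)) ||
      !identical(dim(object@means), dim(object@seasonalOffset)))
    return("means, sds and seasonalOffset must share dimensions")
  if (is.null(rownames(object@means)) || is.null(colnames(object@means)))
    return("means must carry class rownames and band colnames")
  TRUE
})
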