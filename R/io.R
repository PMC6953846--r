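#' @include RasterGrid-methods.R
NULL

# Raster I/O uses the ESRI ASCII grid format (plain text, one file per band)
# plus a JSON sidecar (<base>.aux.json) holding CRS, band names, the nodata
# sentinel and an optional color table. Values are printed with %.17g so a
# write/read round trip is bit-exact for doubles.

fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA
  out
}

writeAsciiBand <- function(mat, file, grid) {
  nr <- nrow(mat); nc <- ncol(mat)
  yll <- grid@ymax - nr * grid@pixelSize
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nc), paste("nrows", nr),
               paste("xllcorner", fmtNum(grid@xmin)),
               paste("yllcorner", fmtNum(yll)),
               paste("cellsize", fmtNum(grid@pixelSize)),
               paste("NODATA_value", fmtNum(grid@nodata))), con)
  body <- matrix(fmtNum(mat), nr, nc)
  body[is.na(mat)] <- fmtNum(grid@nodata)
  writeLines(apply(body, 1L, paste, collapse = " "), con)
}

readAsciiBand <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(file, skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("'%s': expected %d values, found %d", file, nr * nc,
                 length(body)))
  mat <- matrix(body, nr, nc, byrow = TRUE)
  nodata <- vals[["nodata_value"]]
  mat[mat == nodata] <- NA
  list(mat = mat, ncols = nc, nrows = nr, xll = vals[["xllcorner"]],
       yll = vals[["yllcorner"]], cellsize = vals[["cellsize"]],
       nodata = nodata)
}

#' Write a raster to disk (ASCII grid + JSON sidecar)
#'
#' Writes one `<base>_<band>.asc` ESRI ASCII grid per band and a
#' `<base>.aux.json` sidecar with CRS, band order, nodata sentinel and, for
#' category rasters, a color table (one entry per class code). `NA` cells are
#' written as the nodata sentinel.
#'
#' @param grid a [RasterGrid-class].
#' @param path base path (without extension).
#' @param colormap optional named character vector of hex colors, names are
#'   class codes.
#' @return the sidecar path, invisibly.
#' @export
writeRaster <- function(grid, path, colormap = NULL) {
  stopifnot(is(grid, "RasterGrid"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  bn <- bandNames(grid)
  files <- paste0(basename(path), "_", gsub("[^A-Za-z0-9_.-]", "_", bn), ".asc")
  for (i in seq_along(bn))
    writeAsciiBand(grid@values[, , i], file.path(dirname(path), files[i]), grid)
  aux <- list(format = "esri-ascii-grid", crs = grid@crs,
              nodata = grid@nodata, pixel_size = grid@pixelSize,
              xmin = grid@xmin, ymax = grid@ymax,
              bands = lapply(seq_along(bn), function(i)
                list(name = bn[i], file = files[i])))
  if (!is.null(colormap))
    aux$colormap <- as.list(stats::setNames(unname(colormap), names(colormap)))
  sidecar <- paste0(path, ".aux.json")
  jsonlite::write_json(aux, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a raster written by [writeRaster()]
#'
#' @param path the base path, the `.aux.json` sidecar path, or a bare `.asc`
#'   file (read as a single unnamed band with default CRS).
#' @return a [RasterGrid-class]; any colormap travels as attribute
#'   `"colormap"`.
#' @export
readRaster <- function(path) {
  if (grepl("\\.asc$", path)) {
    if (!file.exists(path)) stop(sprintf("cannot read raster '%s'", path))
    b <- readAsciiBand(path)
    g <- RasterGrid(b$mat, bandNames = "layer1", xmin = b$xll,
                    ymax = b$yll + b$nrows * b$cellsize,
                    pixelSize = b$cellsize, nodata = b$nodata)
    return(g)
  }
  sidecar <- if (grepl("\\.aux\\.json$", path)) path else paste0(path, ".aux.json")
  if (!file.exists(sidecar)) stop(sprintf("cannot read raster '%s'", sidecar))
  aux <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
  base <- dirname(sidecar)
  mats <- lapply(aux$bands, function(b) {
    f <- file.path(base, b$file)
    if (!file.exists(f)) stop(sprintf("missing band file '%s'", f))
    readAsciiBand(f)$mat
  })
  arr <- array(unlist(mats), c(dim(mats[[1L]]), length(mats)))
  g <- RasterGrid(arr,
                  bandNames = vapply(aux$bands, function(b) b$name, ""),
                  xmin = aux$xmin, ymax = aux$ymax,
                  pixelSize = aux$pixel_size, crs = aux$crs,
                  nodata = aux$nodata)
  if (!is.null(aux$colormap))
    attr(g, "colormap") <- unlist(aux$colormap)
  g
}

#' Write a land-cover map (codes + embedded color table)
#'
#' @param map a [LandCoverMap-class].
#' @param path base path (without extension).
#' @return sidecar path, invisibly.
#' @export
writeLandCoverMap <- function(map, path) {
  stopifnot(is(map, "LandCoverMap"))
  cm <- legendColors(map@legend)
  writeRaster(map@grid, path, colormap = cm)
}

# ---- vectors: GeoJSON ---------------------------------------------------

geomToGeoJSON <- function(coords, type) {
  switch(type,
    point = list(type = "Point", coordinates = c(coords[1, 1], coords[1, 2])),
    line = list(type = "LineString",
                coordinates = lapply(seq_len(nrow(coords)), function(i)
                  c(coords[i, 1], coords[i, 2]))),
    polygon = {
      ring <- coords
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(i)
             c(ring[i, 1], ring[i, 2]))))
    })
}

#' Write a vector layer as GeoJSON
#'
#' @param layer a [VectorLayer-class].
#' @param path output path (`.geojson`).
#' @return `path`, invisibly.
#' @export
writeVector <- function(layer, path) {
  stopifnot(is(layer, "VectorLayer"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  feats <- lapply(seq_along(layer@geometries), function(i) {
    props <- if (nrow(layer@attributes))
      as.list(layer@attributes[i, , drop = FALSE]) else list()
    list(type = "Feature", properties = props,
         geometry = geomToGeoJSON(layer@geometries[[i]], layer@geomType))
  })
  fc <- list(type = "FeatureCollection", kind = layer@kind, crs = layer@crs,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON vector layer
#'
#' Supports Point, LineString and Polygon features (outer ring only); all
#' features must share one geometry type.
#'
#' @param path a `.geojson` file.
#' @param kind optional semantic role; defaults to the file's `kind` field or
#'   `"generic"`.
#' @return a [VectorLayer-class].
#' @export
readVector <- function(path, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read vector layer '%s'", path))
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- fc$features
  if (!length(feats)) stop(sprintf("'%s' contains no features", path))
  gtypes <- vapply(feats, function(f) f$geometry$type, "")
  type <- switch(gtypes[1L], Point = "point", LineString = "line",
                 Polygon = "polygon",
                 stop("unsupported geometry type: ", gtypes[1L]))
  if (!all(gtypes == gtypes[1L]))
    stop(sprintf("'%s' mixes geometry types", path))
  geoms <- lapply(feats, function(f) {
    cc <- f$geometry$coordinates
    m <- switch(type,
      point = matrix(unlist(cc), 1L, 2L),
      line = do.call(rbind, lapply(cc, unlist)),
      polygon = do.call(rbind, lapply(cc[[1L]], unlist)))
    colnames(m) <- c("x", "y")
    m
  })
  props <- lapply(feats, function(f) f$properties)
  attrs <- if (all(vapply(props, length, 1L) == 0L)) data.frame()
  else do.call(rbind, lapply(props, function(p)
    as.data.frame(lapply(p, function(v) if (is.null(v)) NA else v))))
  new("VectorLayer", geometries = geoms, geomType = type,
      kind = kind %||% (fc$kind %||% "generic"),
      attributes = attrs, crs = fc$crs %||% "local")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
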