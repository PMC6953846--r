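#' @include RasterGrid-methods.R
NULL

# Geometry on the working grid. Membership is decided at pixel centers
# (simple and deterministic); area-fraction tests are out of scope.

## squared distance from each pixel center to the nearest of a set of points
pixelDistToPoints <- function(grid, pts) {
  d <- dim(grid@values)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  xy <- pixelCenters(grid, rc$row, rc$col)
  best <- rep(Inf, nrow(xy))
  for (i in seq_len(nrow(pts))) {
    dd <- (xy[, 1] - pts[i, 1])^2 + (xy[, 2] - pts[i, 2])^2
    best <- pmin(best, dd)
  }
  matrix(sqrt(best), d[1], d[2])
}

## distance from point p to segment (a, b)
segDist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, (wx * vx + wy * vy) / len2))
  sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
}

## distance from each pixel center to the nearest point of a polyline set
pixelDistToLines <- function(grid, lines) {
  d <- dim(grid@values)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  xy <- pixelCenters(grid, rc$row, rc$col)
  best <- rep(Inf, nrow(xy))
  for (ln in lines) {
    for (i in seq_len(nrow(ln) - 1L)) {
      dd <- segDist(xy[, 1], xy[, 2], ln[i, 1], ln[i, 2],
                    ln[i + 1L, 1], ln[i + 1L, 2])
      best <- pmin(best, dd)
    }
  }
  matrix(best, d[1], d[2])
}

## even-odd ray-casting point-in-polygon for one ring
pointInRing <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a vector layer onto a grid
#'
#' Returns a logical matrix over the grid: `TRUE` where a pixel's center is
#' within `radius` metres of a point/line feature (buffer), or inside any
#' polygon (for polygons `radius` defaults to 0: containment).
#'
#' @param layer a [VectorLayer-class].
#' @param grid a [RasterGrid-class] providing the target georeference.
#' @param radius buffer radius in metres (points/lines; optional dilation for
#'   polygons is not supported).
#' @return logical matrix of grid shape.
#' @export
rasterizeLayer <- function(layer, grid, radius = 0) {
  if (!identical(layer@crs, grid@crs))
    stop(sprintf("CRS mismatch between layer '%s' and grid", layer@kind))
  if (layer@geomType == "polygon") {
    d <- dim(grid@values)
    rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
    xy <- pixelCenters(grid, rc$row, rc$col)
    inside <- rep(FALSE, nrow(xy))
    for (ring in layer@geometries)
      inside <- inside | pointInRing(xy[, 1], xy[, 2], ring)
    return(matrix(inside, d[1], d[2]))
  }
  if (radius <= 0)
    stop("points/lines need a positive buffer radius to rasterize")
  dist <- if (layer@geomType == "point")
    pixelDistToPoints(grid, do.call(rbind, layer@geometries))
  else pixelDistToLines(grid, layer@geometries)
  dist <= radius
}

#' Slope from a DEM (Horn's method)
#'
#' Third-order finite difference over the 3x3 neighbourhood on the grid's
#' native resolution; border cells use replicated edges. Cells with any NA
#' neighbour yield NA.
#'
#' @param dem single-band [RasterGrid-class] of elevations in metres.
#' @return [RasterGrid-class] of slope in degrees (band `"slope"`).
#' @export
terrainSlope <- function(dem) {
  z <- gridValues(dem, 1L)
  nr <- nrow(z); nc <- ncol(z)
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  cell <- dem@pixelSize
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cell)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cell)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  gridLike(dem, slope, "slope")
}

#' Otsu threshold of a numeric sample
#'
#' Histogram split maximizing between-class variance, used to separate
#' flooded from non-flooded backscatter when no fixed amplitude threshold is
#' configured. Operates on whatever scale the input provides.
#'
#' @param x numeric values (NAs dropped).
#' @param nbins histogram bins (default 256).
#' @return the threshold (upper edge of the background mode).
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no finite values to threshold")
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate histogram (constant amplitude); supply a fixed threshold")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  sigmaB <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  k <- which.max(sigmaB)
  rng[1] + k * diff(rng) / nbins
}

## QA bit test: TRUE where any of the listed bit positions is set
qaBitSet <- function(qaValues, bits) {
  flagged <- rep(FALSE, length(qaValues))
  for (b in bits)
    flagged <- flagged | (bitwAnd(as.integer(qaValues), bitwShiftL(1L, b)) != 0L)
  flagged
}
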