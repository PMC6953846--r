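#' @include classifier.R
NULL

#' Detect flooded forest in one season's HH amplitude image
#'
#' A pixel is flooded when its HH amplitude exceeds the season's threshold
#' (L-band HH backscatter rises over water under canopy through
#' double-bounce) AND the DEM constraint holds (elevation below the
#' flood-prone lowland cap, optionally also within a corridor distance of a
#' river line). The threshold is either fixed or derived automatically by an
#' Otsu bimodal histogram split restricted to the DEM-constrained region.
#'
#' @param hh single-band [RasterGrid-class] of HH amplitude (any consistent
#'   scale; auto-thresholds are scale-free, fixed thresholds scale-bound).
#' @param dem co-registered DEM [RasterGrid-class].
#' @param demCap elevation cap in metres (default 60).
#' @param threshold `"otsu"` (default) or a fixed numeric amplitude.
#' @param riverLine optional [VectorLayer-class] line; with `corridorM`,
#'   restricts detection to pixels within that distance of the line.
#' @param corridorM corridor half-width in metres.
#' @return logical matrix of flooded pixels; the threshold used is attached
#'   as attribute `"threshold"`.
#' @export
detectFlooded <- function(hh, dem, demCap = 60, threshold = "otsu",
                          riverLine = NULL, corridorM = NULL) {
  stopifnotSameGrid(hh, dem, "HH and DEM")
  amp <- gridValues(hh, 1L)
  el <- gridValues(dem, 1L)
  region <- !is.na(el) & el < demCap
  if (!is.null(riverLine) && !is.null(corridorM))
    region <- region & (pixelDistToLines(hh, riverLine@geometries) <= corridorM)
  thr <- if (identical(threshold, "otsu")) otsuThreshold(amp[region])
  else as.numeric(threshold)
  flooded <- region & !is.na(amp) & amp > thr
  scInfo("detectFlooded: threshold %.4g, %d flooded pixels", thr,
         sum(flooded))
  attr(flooded, "threshold") <- thr
  flooded
}

#' Combine dry- and rainy-season detections into a flood map
#'
#' Permanent = detected in both seasons; seasonal = detected only in the
#' rainy season. Dry-only detections have no definition under this rule;
#' they are treated as not flooded (the conservative choice) and counted as
#' anomalies.
#'
#' @param floodDry,floodRainy logical matrices from [detectFlooded()].
#' @param template [RasterGrid-class] supplying the georeference.
#' @return a [FloodMap-class] (codes 0/1/2 = none/seasonal/permanent).
#' @export
combineSeasons <- function(floodDry, floodRainy, template) {
  if (!identical(dim(floodDry), dim(floodRainy)))
    stop("season grids differ in shape")
  codes <- matrix(0L, nrow(floodDry), ncol(floodDry))
  codes[floodRainy & floodDry] <- 2L
  codes[floodRainy & !floodDry] <- 1L
  anomalies <- sum(floodDry & !floodRainy)
  if (anomalies) scInfo("combineSeasons: %d dry-only anomalies", anomalies)
  new("FloodMap", grid = gridLike(template, codes, "flood"),
      anomalies = as.integer(anomalies))
}

setMethod("show", "FloodMap", function(object) {
  v <- gridValues(object@grid, 1L)
  px <- object@grid@pixelSize
  km2 <- function(n) n * px * px / 1e6
  cat("FloodMap (HH dual-season):\n")
  cat(sprintf("  permanent: %d px (%.2f km2)\n", sum(v == 2L, na.rm = TRUE),
              km2(sum(v == 2L, na.rm = TRUE))))
  cat(sprintf("  seasonal:  %d px (%.2f km2)\n", sum(v == 1L, na.rm = TRUE),
              km2(sum(v == 1L, na.rm = TRUE))))
  cat(sprintf("  dry-only anomalies: %d\n", object@anomalies))
})

#' Convert a flood map into class pixels and shrink the available pool
#'
#' Flooded pixels take the profile's flooded-forest codes before the
#' tree-cover iterations. A flooded pixel already claimed by an earlier
#' class stays with that class (earlier-class precedence); such conflicts
#' are counted.
#'
#' @param floodMap a [FloodMap-class].
#' @param config a [PipelineConfig-class] with `floodCodes`.
#' @param available logical matrix of unassigned pixels.
#' @param which `"seasonal"` or `"permanent"` (or its index), selecting which
#'   flood class to emit.
#' @return list: `mask` logical matrix of newly assigned pixels,
#'   `available` the shrunk pool, `conflicts` count.
#' @export
floodToClassMask <- function(floodMap, config, available,
                             which = c("seasonal", "permanent")) {
  if (!length(config@floodCodes))
    stop("profile legend has no flooded-forest codes")
  if (is.numeric(which)) which <- names(config@floodCodes)[which]
  which <- match.arg(which)
  v <- gridValues(floodMap@grid, 1L)
  want <- v == if (which == "seasonal") 1L else 2L
  want[is.na(want)] <- FALSE
  conflicts <- sum(want & !available)
  if (conflicts)
    scInfo("floodToClassMask[%s]: %d conflicts kept by earlier classes",
           which, conflicts)
  mask <- want & available
  list(mask = mask, available = available & !mask,
       conflicts = as.integer(conflicts))
}
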