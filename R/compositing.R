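#' @include synthetic.R
NULL

#' Remove cloud, shadow and fill pixels using the QA band
#'
#' Any pixel whose QA value has the cloud, shadow or fill bit set (positions
#' given by the QA dialect) is set to `NA` in every band. Fill is treated
#' identically to cloud.
#'
#' @param scene a [SceneStack-class].
#' @param qaDialect named list of bit positions (`cloud`, `shadow`, `fill`);
#'   default is the synthetic dialect (bits 0, 1, 2).
#' @return the masked [SceneStack-class]; the number of removed pixels is
#'   logged and attached as attribute `"removed"`.
#' @export
maskClouds <- function(scene, qaDialect = list(cloud = 0L, shadow = 1L,
                                               fill = 2L)) {
  stopifnotSameGrid(scene@bands, scene@qa, "bands and qa")
  qa <- gridValues(scene@qa, 1L)
  flagged <- matrix(qaBitSet(qa, unlist(qaDialect)), nrow(qa), ncol(qa))
  vals <- scene@bands@values
  for (b in seq_len(dim(vals)[3L])) {
    m <- vals[, , b]; m[flagged] <- NA; vals[, , b] <- m
  }
  out <- scene
  out@bands@values <- vals
  scInfo("maskClouds[%s]: removed %d of %d pixels", format(scene@date),
         sum(flagged), length(flagged))
  attr(out, "removed") <- sum(flagged)
  out
}

## season-year of a date: December belongs to the window starting that year
drySeasonYear <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m == 12L, y, y - 1L)
}

#' Select the scenes of a compositing window
#'
#' Seasonal style (Liberia): keeps dry-season scenes whose date falls in a
#' December-March window for the central season-year plus/minus one.
#' Annual style (Gabon): keeps all scenes of the central year plus/minus one.
#'
#' @param collection list of [SceneStack-class].
#' @param window list with `style` (`"seasonal"`/`"annual"`), `centerYear`,
#'   and `season` (seasonal style).
#' @return the selected sub-list (error if empty).
#' @export
selectWindow <- function(collection, window) {
  dates <- as.Date(vapply(collection, function(s) format(s@date), ""))
  keep <- if (identical(window$style, "seasonal")) {
    m <- as.integer(format(dates, "%m"))
    sy <- drySeasonYear(dates)
    seas <- vapply(collection, function(s) s@season, "")
    m %in% c(12L, 1L, 2L, 3L) & seas == (window$season %||% "dry") &
      sy >= window$centerYear - 1L & sy <= window$centerYear + 1L
  } else {
    y <- as.integer(format(dates, "%Y"))
    y >= window$centerYear - 1L & y <= window$centerYear + 1L
  }
  scInfo("selectWindow: %d of %d scenes selected", sum(keep), length(keep))
  if (!any(keep)) stop("compositing window selects no scenes")
  collection[keep]
}

#' Per-band per-pixel median composite
#'
#' Median of the non-missing observations per pixel and band; an even count
#' gives the mean of the two middle values. Pixels with zero valid
#' observations in every band are gaps (`NA` everywhere, `validCount` 0).
#'
#' @param scenes non-empty list of co-registered [SceneStack-class]
#'   (typically already cloud-masked).
#' @return a [Composite-class].
#' @export
medianComposite <- function(scenes) {
  if (!length(scenes)) stop("no scenes to composite")
  ref <- scenes[[1L]]@bands
  for (s in scenes[-1L]) stopifnotSameGrid(ref, s@bands, "scenes")
  bn <- bandNames(ref)
  d <- dim(ref@values)
  k <- length(scenes)
  out <- array(NA_real_, d, dimnames = list(NULL, NULL, bn))
  validObs <- matrix(0L, d[1], d[2])
  for (b in seq_along(bn)) {
    stack <- vapply(scenes, function(s) as.vector(s@bands@values[, , b]),
                    numeric(d[1] * d[2]))
    stack <- matrix(stack, ncol = k)
    med <- apply(stack, 1L, stats::median, na.rm = TRUE)
    med[is.nan(med)] <- NA
    out[, , b] <- matrix(med, d[1], d[2])
    if (b == 1L) validObs <- matrix(rowSums(!is.na(stack)), d[1], d[2])
    else validObs <- pmax(validObs, matrix(rowSums(!is.na(stack)), d[1], d[2]))
  }
  gap <- validObs == 0L
  for (b in seq_along(bn)) { m <- out[, , b]; m[gap] <- NA; out[, , b] <- m }
  comp <- new("Composite",
              bands = RasterGrid(out, bandNames = bn, xmin = ref@xmin,
                                 ymax = ref@ymax, pixelSize = ref@pixelSize,
                                 crs = ref@crs, nodata = ref@nodata),
              validCount = gridLike(ref, validObs, "valid_count"))
  scInfo("medianComposite: %d scenes, %d gap pixels (%.1f%%)", k, sum(gap),
         100 * mean(gap))
  comp
}

#' @rdname gapMask
setMethod("gapMask", "Composite", function(x)
  gridValues(x@validCount, 1L) == 0L)

setMethod("show", "Composite", function(object) {
  d <- dim(object@bands@values)
  cat(sprintf("Composite: %d x %d pixels, bands [%s]\n", d[1], d[2],
              paste(bandNames(object@bands), collapse = ", ")))
  cat(sprintf("  gap pixels: %d (%.2f%%)\n", sum(gapMask(object)),
              100 * mean(gapMask(object))))
})
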