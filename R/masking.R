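#' @include indices.R
NULL

#' Per-class signatures of bands and indices at sample pixels
#'
#' Computes mean and SD per class and layer at the sampled pixels, and keeps
#' the raw per-class sample values so thresholds can be suggested from them.
#'
#' @param samples data.frame with `row`, `col`, `name` (class) columns, e.g.
#'   from [sampleTraining()].
#' @param composite a [Composite-class].
#' @param indexStack optional [IndexStack-class].
#' @param layers layer names to profile (default: bands plus any computed
#'   indices).
#' @return object of class `classSignatures`: list with `table` (data.frame
#'   class, layer, mean, sd, n) and `values` (values[[class]][[layer]]).
#'   `write.csv(x$table, ...)` persists it.
#' @export
deriveSignatures <- function(samples, composite, indexStack = NULL,
                             layers = NULL) {
  if (is.null(layers))
    layers <- c(bandNames(composite@bands),
                if (!is.null(indexStack)) bandNames(indexStack))
  classes <- unique(samples$name)
  empty <- classes[!classes %in% samples$name[!is.na(samples$row)]]
  if (!nrow(samples)) stop("no sample pixels supplied")
  mats <- lapply(layers, lookupLayer, composite = composite,
                 indexStack = indexStack)
  names(mats) <- layers
  values <- list(); rows <- list()
  for (cl in classes) {
    s <- samples[samples$name == cl, , drop = FALSE]
    if (!nrow(s)) stop(sprintf("class '%s' has zero sample pixels", cl))
    idx <- cbind(s$row, s$col)
    values[[cl]] <- lapply(mats, function(m) m[idx])
    for (ly in layers) {
      v <- values[[cl]][[ly]]
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, layer = ly, mean = mean(v, na.rm = TRUE),
        sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else 0,
        n = sum(!is.na(v)))
    }
  }
  structure(list(table = do.call(rbind, rows), values = values),
            class = "classSignatures")
}

#' @export
print.classSignatures <- function(x, ...) {
  cat(sprintf("classSignatures: %d classes x %d layers\n",
              length(x$values), length(x$values[[1L]])))
  invisible(x)
}

#' Suggest a zero-omission Phase-I threshold
#'
#' Returns the loosest strict threshold on one layer that retains every
#' target-class sample pixel: the comparator points toward the target's side
#' of the layer distribution (`">"` when the target mean exceeds the pooled
#' mean of the other classes), and the threshold sits `margin` beyond the
#' most extreme target sample, so it is never tighter than any target value.
#' A layer with no separation (all class means equal) is flagged
#' non-discriminative with a warning.
#'
#' @param signatures a `classSignatures` object from [deriveSignatures()].
#' @param targetClass class name.
#' @param layer layer name.
#' @param margin slack beyond the extreme target sample (default 1e-6, keeps
#'   the strict inequality true at the sample itself).
#' @return a [MaskRule-class]; `@params$nonDiscriminative` is TRUE when
#'   flagged.
#' @export
suggestThreshold <- function(signatures, targetClass, layer,
                             margin = 1e-6) {
  if (!targetClass %in% names(signatures$values))
    stop(sprintf("class '%s' absent from signatures", targetClass))
  tv <- signatures$values[[targetClass]][[layer]]
  tv <- tv[!is.na(tv)]
  if (!length(tv)) stop(sprintf("no finite '%s' values for '%s'", layer,
                                targetClass))
  others <- setdiff(names(signatures$values), targetClass)
  ov <- unlist(lapply(others, function(cl) signatures$values[[cl]][[layer]]))
  ov <- ov[!is.na(ov)]
  dir <- if (length(ov) && mean(tv) < mean(ov)) "<" else ">"
  thr <- if (dir == ">") min(tv) - margin else max(tv) + margin
  rule <- spectralRule(layer, dir, thr)
  if (length(ov) && isTRUE(all.equal(stats::var(c(tv, ov)), 0))) {
    warning(sprintf("layer '%s' shows no separation; rule flagged", layer))
    rule@params$nonDiscriminative <- TRUE
  }
  rule
}

applySpectralRule <- function(rule, composite, indexStack) {
  m <- lookupLayer(rule@layer, composite, indexStack)
  ok <- if (rule@comparator == ">") m > rule@threshold else m < rule@threshold
  ok & !is.na(m)
}

#' Masking Phase I: spectral threshold filtering
#'
#' Intersects the available pixels with every spectral rule (logical AND;
#' rule order is immaterial). NA layer values never qualify. Retained and
#' removed counts are logged and attached as attribute `"provenance"`.
#'
#' @param composite a [Composite-class].
#' @param indexStack an [IndexStack-class].
#' @param rules list of spectral [MaskRule-class].
#' @param available logical matrix of currently unassigned, non-gap pixels.
#' @return logical candidate matrix.
#' @export
applyPhase1 <- function(composite, indexStack, rules, available) {
  cand <- available
  prov <- list()
  for (rule in rules) {
    if (rule@kind != "spectral") stop("applyPhase1 takes spectral rules only")
    cand <- cand & applySpectralRule(rule, composite, indexStack)
    prov[[length(prov) + 1L]] <- data.frame(
      rule = sprintf("%s %s %g", rule@layer, rule@comparator, rule@threshold),
      retained = sum(cand))
  }
  scInfo("phase1: %d rules, retained %d of %d available", length(rules),
         sum(cand), sum(available))
  attr(cand, "provenance") <- if (length(prov)) do.call(rbind, prov)
  cand
}

#' Masking Phase II: ancillary spatial constraints
#'
#' Intersects Phase-I candidates with spatial constraints: buffers around
#' point/line layers (pixel-center membership), polygon containment, DEM
#' elevation caps, and `after_class_removed` ordering dependencies (an error
#' if the named class has not been mapped yet).
#'
#' @param candidate logical matrix from [applyPhase1()].
#' @param rules list of spatial [MaskRule-class].
#' @param template a [RasterGrid-class] supplying the georeference.
#' @param vectors named list of [VectorLayer-class] ancillary layers.
#' @param dem optional DEM [RasterGrid-class].
#' @param assigned named list of logical matrices of already-mapped classes.
#' @return logical candidate matrix.
#' @export
applyPhase2 <- function(candidate, rules, template, vectors = list(),
                        dem = NULL, assigned = list()) {
  for (rule in rules) {
    if (rule@kind != "spatial") stop("applyPhase2 takes spatial rules only")
    candidate <- candidate & switch(rule@constraint,
      within_buffer = {
        ly <- vectors[[rule@layer]]
        if (is.null(ly))
          stop(sprintf("missing ancillary layer '%s' for within_buffer",
                       rule@layer))
        rasterizeLayer(ly, template, radius = rule@params$radius)
      },
      within_polygons = {
        ly <- vectors[[rule@layer]]
        if (is.null(ly))
          stop(sprintf("missing ancillary layer '%s' for within_polygons",
                       rule@layer))
        rasterizeLayer(ly, template)
      },
      elevation_below = {
        if (is.null(dem)) stop("elevation_below rule needs a DEM")
        m <- gridValues(dem, 1L) < rule@params$cap
        m & !is.na(m)
      },
      after_class_removed = {
        cl <- rule@params$class
        if (!cl %in% names(assigned))
          stop(sprintf("class must be mapped after '%s' (not yet mapped)", cl))
        !assigned[[cl]]
      },
      stop(sprintf("unhandled constraint '%s'", rule@constraint)))
  }
  scInfo("phase2: %d rules, retained %d pixels", length(rules), sum(candidate))
  candidate
}
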