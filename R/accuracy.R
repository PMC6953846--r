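#' @include sar.R
NULL

#' Stratified random validation sampling
#'
#' Draws up to `nPerClass` pixels per mapped class, uniformly without
#' replacement within each stratum (each sample is one 30 m x 30 m pixel
#' footprint). Shortfalls in small classes are logged.
#'
#' @param map a [LandCoverMap-class].
#' @param nPerClass samples per class (default 50).
#' @param seed integer seed (same seed gives identical samples).
#' @return data.frame: `row`, `col`, `x`, `y` (pixel-center map
#'   coordinates), `mapCode`, `mapClass`.
#' @export
stratifiedSample <- function(map, nPerClass = 50L, seed = 1L) {
  v <- gridValues(map@grid, 1L)
  present <- intersect(legendCodes(map@legend), unique(as.vector(v)))
  if (!length(present)) stop("map contains no legend classes to sample")
  set.seed(as.integer(seed))
  out <- lapply(present, function(code) {
    idx <- which(v == code)
    n <- min(nPerClass, length(idx))
    if (n < nPerClass)
      scInfo("stratifiedSample: class %d has only %d pixels (< %d)",
             code, length(idx), nPerClass)
    take <- if (length(idx) == 1L) idx else sample(idx, n)
    row <- ((take - 1L) %% nrow(v)) + 1L
    col <- ((take - 1L) %/% nrow(v)) + 1L
    xy <- pixelCenters(map@grid, row, col)
    data.frame(row = row, col = col, x = xy[, 1], y = xy[, 2],
               mapCode = code, mapClass = nameForCode(map@legend, code))
  })
  do.call(rbind, out)
}

#' Attach reference labels from a truth raster
#'
#' @param samples data.frame from [stratifiedSample()].
#' @param reference a [LandCoverMap-class] (e.g. the generator's truth) on
#'   the same grid.
#' @return `samples` with `refCode` and `refClass` columns.
#' @export
labelFromTruth <- function(samples, reference) {
  v <- gridValues(reference@grid, 1L)
  samples$refCode <- v[cbind(samples$row, samples$col)]
  samples$refClass <- nameForCode(reference@legend, samples$refCode)
  samples
}

#' Build an error matrix from labelled samples
#'
#' Cell (r, m) counts samples with reference class r and map class m.
#'
#' @param samples data.frame with `refClass` and `mapClass` columns (labels
#'   must belong to the legend), or two label vectors via `ref`/`map`.
#' @param legend a [ClassLegend-class] fixing class order; defaults to the
#'   observed labels.
#' @param ref,map alternative interface: character/factor label vectors.
#' @return an [ErrorMatrix-class].
#' @export
buildErrorMatrix <- function(samples = NULL, legend = NULL, ref = NULL,
                             map = NULL) {
  if (!is.null(samples)) { ref <- samples$refClass; map <- samples$mapClass }
  if (is.null(ref) || is.null(map) || length(ref) != length(map))
    stop("need paired reference and map labels")
  lv <- if (!is.null(legend)) legendNames(legend)
  else sort(unique(c(as.character(ref), as.character(map))))
  bad <- setdiff(unique(c(as.character(ref), as.character(map))), lv)
  if (length(bad))
    stop(sprintf("labels outside the legend: %s", paste(bad, collapse = ", ")))
  m <- table(factor(ref, levels = lv), factor(map, levels = lv))
  counts <- matrix(as.integer(m), nrow(m), ncol(m),
                   dimnames = list(lv, lv))
  new("ErrorMatrix", counts = counts)
}

setMethod("show", "ErrorMatrix", function(object) {
  cat(sprintf("ErrorMatrix: %d classes, n = %d (reference rows x map columns)\n",
              nrow(object@counts), sum(object@counts)))
  print(object@counts)
})

wilsonCI <- function(k, n, level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  # only the interval is used; the chi-squared small-count warning concerns
  # the test statistic, not the Wilson bounds
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = level, correct = FALSE))$conf.int
  c(ci[1], ci[2])
}

#' Accuracy statistics of an error matrix
#'
#' Overall accuracy (trace/n), per-class user's accuracy (diagonal over map
#' column total; 1 - commission), producer's accuracy (diagonal over
#' reference row total; 1 - omission), and the binary-class (Portmanteau)
#' accuracy: the overall accuracy after collapsing the matrix to the class
#' of interest versus all others. Confidence intervals are Wilson score
#' intervals (better coverage than Wald at stratum sizes near 50); a Wald
#' option is available for comparison. A zero marginal makes the statistic
#' undefined (NA), not 0. Stored values are unrounded; `print()` applies
#' display rounding (overall to the nearest integer percent, per-class to
#' one decimal).
#'
#' @param em an [ErrorMatrix-class].
#' @param ciLevel confidence level (default 0.95).
#' @param ciMethod `"wilson"` (default) or `"wald"`.
#' @return object of class `accuracyStats`: list with `n`, `overall`
#'   (proportion), `overallCI`, and `perClass` data.frame (`class`, `users`,
#'   `producers`, `portmanteau`, CI bounds), all as proportions.
#' @export
accuracyStats <- function(em, ciLevel = 0.95, ciMethod = c("wilson", "wald")) {
  ciMethod <- match.arg(ciMethod)
  m <- em@counts
  n <- sum(m)
  if (n == 0L) stop("empty error matrix")
  ci <- function(k, nn) {
    if (nn == 0L) return(c(NA_real_, NA_real_))
    if (ciMethod == "wilson") wilsonCI(k, nn, ciLevel)
    else {
      p <- k / nn
      z <- stats::qnorm(1 - (1 - ciLevel) / 2)
      c(max(0, p - z * sqrt(p * (1 - p) / nn)),
        min(1, p + z * sqrt(p * (1 - p) / nn)))
    }
  }
  overall <- sum(diag(m)) / n
  oci <- ci(sum(diag(m)), n)
  per <- lapply(seq_len(nrow(m)), function(i) {
    colTot <- sum(m[, i]); rowTot <- sum(m[i, ])
    users <- if (colTot > 0L) m[i, i] / colTot else NA_real_
    producers <- if (rowTot > 0L) m[i, i] / rowTot else NA_real_
    tp <- m[i, i]; tn <- n - rowTot - colTot + m[i, i]
    uci <- if (colTot > 0L) ci(m[i, i], colTot) else c(NA_real_, NA_real_)
    pci <- if (rowTot > 0L) ci(m[i, i], rowTot) else c(NA_real_, NA_real_)
    data.frame(class = rownames(m)[i], users = users, producers = producers,
               portmanteau = (tp + tn) / n,
               usersLo = uci[1], usersHi = uci[2],
               producersLo = pci[1], producersHi = pci[2])
  })
  structure(list(n = n, overall = overall, overallCI = oci,
                 perClass = do.call(rbind, per), ciMethod = ciMethod,
                 ciLevel = ciLevel),
            class = "accuracyStats")
}

#' @export
print.accuracyStats <- function(x, ...) {
  cat(sprintf("Overall accuracy: %d%% (n = %d; %.0f%% CI %.1f-%.1f%%)\n",
              round(100 * x$overall), x$n, 100 * x$ciLevel,
              100 * x$overallCI[1], 100 * x$overallCI[2]))
  p <- x$perClass
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-26s user's %5.1f%%  producer's %5.1f%%  binary %5.1f%%\n",
                p$class[i], 100 * p$users[i], 100 * p$producers[i],
                100 * p$portmanteau[i]))
  invisible(x)
}

#' Per-class areas of a categorical map
#'
#' km2 = pixel count x pixel area (0.0009 km2 for 30-m pixels), exactly.
#'
#' @param map a [LandCoverMap-class] or [FloodMap-class].
#' @return data.frame: `code`, `class`, `pixels`, `km2`.
#' @export
classAreas <- function(map) {
  v <- gridValues(map@grid, 1L)
  pxKm2 <- (map@grid@pixelSize / 1000)^2
  if (is(map, "FloodMap")) {
    codes <- c(1L, 2L); nms <- c("seasonal", "permanent")
  } else {
    codes <- legendCodes(map@legend); nms <- legendNames(map@legend)
  }
  counts <- vapply(codes, function(cd) sum(v == cd, na.rm = TRUE), integer(1))
  data.frame(code = codes, class = nms, pixels = counts,
             km2 = counts * pxKm2)
}

#' Compare per-class areas between two maps
#'
#' @param a,b area tables from [classAreas()] (or any data.frame with
#'   `class` and `km2`); pixel scale must match upstream.
#' @param class optional class name to extract a single delta.
#' @return data.frame of per-class `km2A`, `km2B`, `deltaKm2` (= a - b), or
#'   a single numeric delta when `class` is given.
#' @export
compareAreas <- function(a, b, class = NULL) {
  merged <- merge(a[, c("class", "km2")], b[, c("class", "km2")],
                  by = "class", suffixes = c("A", "B"), all = TRUE)
  merged$km2A[is.na(merged$km2A)] <- 0
  merged$km2B[is.na(merged$km2B)] <- 0
  merged$deltaKm2 <- merged$km2A - merged$km2B
  if (!is.null(class)) {
    i <- match(class, merged$class)
    if (is.na(i)) stop(sprintf("class '%s' absent from both maps", class))
    return(merged$deltaKm2[i])
  }
  merged
}
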