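#' @include masking.R
NULL

#' Train a binary random forest (class vs other)
#'
#' A 100-tree (configurable) majority-vote ensemble; each split draws a
#' random predictor subset of size `mtry` (default: square root of the
#' predictor count). Out-of-bag accuracy is logged.
#'
#' @param x data.frame/matrix of predictor values.
#' @param y factor with exactly the levels `"class"` and `"other"`.
#' @param trees number of trees (default 100).
#' @param mtry predictors tried per split (default `floor(sqrt(ncol(x)))`).
#' @param seed integer seed (training is seed-deterministic).
#' @param minPerLabel minimum training pixels per label (default 10).
#' @return a fitted `randomForest` model.
#' @export
trainBinaryRF <- function(x, y, trees = 100L, mtry = NULL, seed = 1L,
                          minPerLabel = 10L) {
  y <- factor(y, levels = c("class", "other"))
  tab <- table(y)
  if (any(tab == 0L))
    stop("training set must contain both 'class' and 'other' pixels")
  if (any(tab < minPerLabel))
    stop(sprintf("need >= %d training pixels per label (have %s)",
                 minPerLabel, paste(tab, collapse = "/")))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = as.data.frame(x), y = y,
                                    ntree = as.integer(trees), mtry = mtry)
  oob <- 1 - fit$err.rate[fit$ntree, "OOB"]
  scInfo("trainBinaryRF: n=%d p=%d trees=%d OOB accuracy=%.3f", length(y),
         ncol(x), trees, oob)
  fit
}

## predictor matrix at pixel (row, col) positions
predictorMatrix <- function(rows, cols, predictors, composite, indexStack) {
  idx <- cbind(rows, cols)
  out <- lapply(predictors, function(p)
    lookupLayer(p, composite, indexStack)[idx])
  names(out) <- predictors
  as.data.frame(out)
}

#' Mask, train and classify one class
#'
#' Applies the class's Phase-I/II masking to the available pool, assembles
#' the binary training set (target-class training pixels vs non-target
#' pixels restricted to the candidate mask, falling back to unrestricted
#' non-target pixels when fewer than the floor remain), trains the binary
#' random forest and predicts the candidate pixels. Pixels outside the
#' candidate mask are never assigned; candidates predicted "other" return to
#' the pool.
#'
#' @param composite a [Composite-class].
#' @param indexStack an [IndexStack-class].
#' @param spec the class's [ClassSpec-class].
#' @param available logical matrix of unassigned, non-gap pixels.
#' @param config a [PipelineConfig-class].
#' @param training data.frame (`row`, `col`, `name`) of training pixels.
#' @param vectors,dem,assigned ancillary layers for Phase II (see
#'   [applyPhase2()]).
#' @return list: `assigned` logical matrix, `candidates` count, `model` (or
#'   NULL when the class was skipped), `trainingSize`.
#' @export
classifyClass <- function(composite, indexStack, spec, available, config,
                          training, vectors = list(), dem = NULL,
                          assigned = list()) {
  cand <- applyPhase1(composite, indexStack, spec@phase1, available)
  cand <- applyPhase2(cand, spec@phase2, composite@bands, vectors, dem,
                      assigned)
  if (!any(cand)) {
    warning(sprintf("class '%s': empty candidate mask, skipped", spec@name))
    return(list(assigned = cand, candidates = 0L, model = NULL,
                trainingSize = 0L))
  }
  tgt <- training[training$name == spec@name, , drop = FALSE]
  oth <- training[training$name != spec@name, , drop = FALSE]
  inCand <- cand[cbind(oth$row, oth$col)]
  floor <- config@params$minTrainPerLabel
  othUse <- if (sum(inCand) >= floor) oth[inCand, , drop = FALSE] else oth
  x <- rbind(
    predictorMatrix(tgt$row, tgt$col, spec@predictors, composite, indexStack),
    predictorMatrix(othUse$row, othUse$col, spec@predictors, composite,
                    indexStack))
  y <- factor(rep(c("class", "other"), c(nrow(tgt), nrow(othUse))),
              levels = c("class", "other"))
  keep <- stats::complete.cases(x)
  model <- trainBinaryRF(x[keep, , drop = FALSE], y[keep],
                         trees = config@trees, seed = config@seed,
                         minPerLabel = floor)
  ci <- which(cand)
  rows <- ((ci - 1L) %% nrow(cand)) + 1L
  cols <- ((ci - 1L) %/% nrow(cand)) + 1L
  px <- predictorMatrix(rows, cols, spec@predictors, composite, indexStack)
  ok <- stats::complete.cases(px)
  pred <- rep("other", length(ci))
  if (any(ok))
    pred[ok] <- as.character(stats::predict(model, px[ok, , drop = FALSE]))
  out <- matrix(FALSE, nrow(cand), ncol(cand))
  out[ci[pred == "class"]] <- TRUE
  scInfo("classifyClass[%s]: %d candidates -> %d assigned", spec@name,
         length(ci), sum(out))
  list(assigned = out, candidates = sum(cand), model = model,
       trainingSize = sum(keep))
}

#' Knowledge-based verification of a classified class
#'
#' Reverts assigned pixels that violate a verification rule (currently
#' `slope_below`: e.g. water or mangroves on steep terrain) back to "other".
#'
#' @param assigned logical matrix of the class's pixels.
#' @param rules list of verification [MaskRule-class] (empty = identity).
#' @param dem DEM [RasterGrid-class] (required by slope rules).
#' @return logical matrix; reversion count attached as attribute
#'   `"reverted"` and logged.
#' @export
verifyClass <- function(assigned, rules = list(), dem = NULL) {
  reverted <- 0L
  for (rule in rules) {
    if (rule@constraint == "slope_below") {
      if (is.null(dem)) stop("slope verification needs a DEM")
      slope <- gridValues(terrainSlope(dem), 1L)
      bad <- assigned & !is.na(slope) & slope > rule@params$cap
      reverted <- reverted + sum(bad)
      assigned[bad] <- FALSE
    }
  }
  if (length(rules)) scInfo("verifyClass: reverted %d pixels", reverted)
  attr(assigned, "reverted") <- reverted
  assigned
}

#' Remove a newly mapped class from the available pool
#'
#' @param available logical matrix of unassigned pixels.
#' @param newClass logical matrix of the class just mapped; must be a subset
#'   of `available` (an overlap with an already-assigned pixel is an
#'   invariant breach and a hard error).
#' @return the shrunk available matrix.
#' @export
propagateMask <- function(available, newClass) {
  if (any(newClass & !available))
    stop("invariant breach: class assigns pixels outside the available pool")
  available & !newClass
}

#' Composite per-class rasters into a single land-cover map
#'
#' @param classRasters named list (class name -> logical matrix), pairwise
#'   disjoint.
#' @param legend a [ClassLegend-class].
#' @param template [RasterGrid-class] supplying the georeference.
#' @param gap logical matrix of nodata/gap pixels (NA in the map).
#' @param provenance optional list stored on the map.
#' @return a [LandCoverMap-class]; unassigned non-gap pixels carry code 0.
#' @export
compositeMap <- function(classRasters, legend, template, gap = NULL,
                         provenance = list()) {
  d <- dim(template@values)[1:2]
  codes <- matrix(0L, d[1], d[2])
  claimed <- matrix(FALSE, d[1], d[2])
  for (nm in names(classRasters)) {
    m <- classRasters[[nm]]
    if (any(m & claimed)) stop("class rasters overlap; disjointness violated")
    codes[m] <- codeForName(legend, nm)
    claimed <- claimed | m
  }
  if (!is.null(gap)) codes[gap] <- NA_integer_
  new("LandCoverMap", grid = gridLike(template, codes, "code"),
      legend = legend, provenance = provenance)
}

setMethod("show", "LandCoverMap", function(object) {
  v <- gridValues(object@grid, 1L)
  d <- dim(v)
  cat(sprintf("LandCoverMap: %d x %d pixels, %d-class legend\n", d[1], d[2],
              nrow(object@legend@entries)))
  tab <- table(factor(v, levels = c(0L, legendCodes(object@legend))))
  nm <- c("unclassified", legendNames(object@legend))
  for (i in seq_along(tab))
    cat(sprintf("  %-26s %7d px\n", nm[i], tab[i]))
  if (any(is.na(v))) cat(sprintf("  %-26s %7d px\n", "nodata/gap", sum(is.na(v))))
})

#' Run the sequential binary classification
#'
#' The pipeline's core loop: iterate over classes in the configured order;
#' for each, mask (Phases I and II), train the binary random forest, classify
#' the candidates, verify, store the class and remove its pixels from the
#' pool. Flood codes in the order are filled from the supplied SAR flood map
#' (before the tree-cover iterations in the Gabon profile), with
#' earlier-class precedence on conflicts. Finally all classes are composited
#' into a single map; never-assigned pixels remain unclassified (0), gap
#' pixels NA.
#'
#' @param composite a [Composite-class].
#' @param indexStack an [IndexStack-class].
#' @param config a [PipelineConfig-class].
#' @param training data.frame of training pixels (`row`, `col`, `name`).
#' @param vectors named list of ancillary [VectorLayer-class].
#' @param dem DEM [RasterGrid-class].
#' @param floodMap optional [FloodMap-class] (Gabon).
#' @return a [LandCoverMap-class] with per-class provenance.
#' @export
runSequentialClassification <- function(composite, indexStack, config,
                                        training, vectors = list(),
                                        dem = NULL, floodMap = NULL) {
  gap <- gapMask(composite)
  available <- !gap
  assigned <- list()
  prov <- list(seed = config@seed, country = config@country)
  iter <- 0L
  for (code in config@order) {
    iter <- iter + 1L
    if (code %in% config@floodCodes) {
      if (is.null(floodMap)) {
        warning("flood code in classification order but no flood map supplied")
        next
      }
      res <- floodToClassMask(floodMap, config, available,
                              which(config@floodCodes == code))
      assigned[[nameForCode(config@legend, code)]] <- res$mask
      available <- res$available
      prov[[nameForCode(config@legend, code)]] <-
        list(iteration = iter, source = "sar", pixels = sum(res$mask),
             conflicts = res$conflicts)
      next
    }
    spec <- config@specs[[nameForCode(config@legend, code)]]
    res <- classifyClass(composite, indexStack, spec, available, config,
                         training, vectors, dem, assigned)
    cls <- verifyClass(res$assigned, spec@verify, dem)
    cls <- cls & available   # verification can only shrink
    assigned[[spec@name]] <- cls
    available <- propagateMask(available, cls)
    prov[[spec@name]] <- list(iteration = iter, pixels = sum(cls),
                              candidates = res$candidates,
                              trainingSize = res$trainingSize)
  }
  compositeMap(assigned, config@legend, composite@bands, gap = gap,
               provenance = prov)
}
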