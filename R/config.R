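#' @include legend.R
NULL

# bands and indices known to the pipeline; rules may cite any of these
KNOWN_BANDS <- c("B2", "B3", "B4", "B5", "B6", "B7", "B10")
KNOWN_INDICES <- c("NDMI", "MNDWI", "NDBI", "NDII", "NDBaI", "BI", "UI",
                   "NDVI", "GCVI", "SR", "R75", "R65", "R34")

scInfo <- function(...) {
  if (identical(getOption("SeqCover.logLevel", "info"), "info"))
    message(sprintf(...))
  invisible(NULL)
}

#' Construct masking rules
#'
#' `spectralRule()` builds a Phase-I threshold rule on a band or index
#' (strict inequality, exactly as threshold tables print them).
#' `spatialRule()` builds a Phase-II ancillary constraint.
#'
#' @param layer band/index name (spectral) or ancillary layer name (spatial:
#'   the name of a vector layer, the DEM, or a class name for
#'   `after_class_removed`).
#' @param comparator `">"` or `"<"`.
#' @param threshold numeric threshold.
#' @param constraint one of `"within_buffer"`, `"within_polygons"`,
#'   `"elevation_below"`, `"slope_below"`, `"after_class_removed"`.
#' @param radius buffer radius in metres (`within_buffer`).
#' @param cap elevation (m) or slope (degrees) cap.
#' @param class class name (`after_class_removed`).
#' @return a [MaskRule-class].
#' @aliases spatialRule
#' @export
spectralRule <- function(layer, comparator, threshold) {
  if (!layer %in% c(KNOWN_BANDS, KNOWN_INDICES))
    stop(sprintf("rule cites unknown band/index '%s'", layer))
  new("MaskRule", kind = "spectral", layer = layer, comparator = comparator,
      threshold = threshold)
}

#' @rdname spectralRule
#' @export
spatialRule <- function(constraint, layer = NA_character_, radius = NULL,
                        cap = NULL, class = NULL) {
  params <- list()
  if (!is.null(radius)) params$radius <- radius
  if (!is.null(cap)) params$cap <- cap
  if (!is.null(class)) params$class <- class
  new("MaskRule", kind = "spatial", layer = layer, constraint = constraint,
      params = params)
}

#' Construct a class specification
#'
#' @param code legend code.
#' @param name class name.
#' @param phase1,phase2,verify lists of [MaskRule-class] objects.
#' @param predictors character vector of band/index layer names.
#' @return a [ClassSpec-class].
#' @export
ClassSpec <- function(code, name, phase1 = list(), phase2 = list(),
                      predictors = KNOWN_BANDS, verify = list()) {
  bad <- setdiff(predictors, c(KNOWN_BANDS, KNOWN_INDICES))
  if (length(bad))
    stop(sprintf("unknown predictor layer(s): %s", paste(bad, collapse = ", ")))
  new("ClassSpec", code = as.integer(code), name = name, phase1 = phase1,
      phase2 = phase2, predictors = predictors, verify = verify)
}

catWater <- c("NDMI", "MNDWI")
catBuilt <- c("NDBI", "NDII", "NDBaI", "BI", "UI")
catVeg <- c("NDVI", "GCVI", "SR")
catRatio <- c("R75", "R65", "R34")

#' Country mapping profiles
#'
#' Returns the fully resolved default configuration for a country: its
#' 10-class legend, per-class Phase-I spectral thresholds and Phase-II
#' ancillary constraints, per-class predictor sets, the classification order,
#' the compositing window style, and classifier/sampling settings
#' (100 trees, 50 validation samples per class).
#'
#' Tunable scalars live in `params`: `settlementBufferM` (the settlement
#' buffer radius used to constrain artificial surfaces; no canonical value
#' exists, the 2000 m default is a calibration knob), `shoreBufferM` (1000),
#' `slopeCapDeg` (verification cap for water/mangroves, 10), `demCapM`
#' (mangrove elevation cap, 95), `floodDemCapM` (flood-prone lowland cap,
#' 60), `minTrainPerLabel` (10) and `denomEps` (1e-10).
#'
#' @param country `"liberia"` or `"gabon"`.
#' @param seed integer random seed recorded in outputs.
#' @return a [PipelineConfig-class].
#' @export
countryProfile <- function(country = c("liberia", "gabon"), seed = 1L) {
  country <- match.arg(country)
  params <- list(settlementBufferM = 2000, shoreBufferM = 1000,
                 slopeCapDeg = 10, demCapM = 95, floodDemCapM = 60,
                 minTrainPerLabel = 10L, denomEps = 1e-10)
  slopeVerify <- list(spatialRule("slope_below", cap = params$slopeCapDeg))
  if (country == "liberia") {
    legend <- liberiaLegend()
    specs <- list(
      ClassSpec(1, "water", list(spectralRule("MNDWI", ">", -0.2)),
                predictors = c(KNOWN_BANDS, catWater), verify = slopeVerify),
      ClassSpec(2, "mangroves_wetlands",
                list(spectralRule("MNDWI", ">", -0.35),
                     spectralRule("NDVI", ">", 0.3)),
                predictors = c(KNOWN_BANDS, catWater, catVeg),
                verify = slopeVerify),
      ClassSpec(3, "artificial_surfaces",
                list(spectralRule("B6", ">", 0.25),
                     spectralRule("NDVI", "<", 0.45)),
                phase2 = list(spatialRule("within_buffer", "settlements",
                                          radius = params$settlementBufferM)),
                predictors = c(KNOWN_BANDS, catBuilt)),
      ClassSpec(4, "barren_land",
                list(spectralRule("B6", ">", 0.25),
                     spectralRule("NDVI", "<", 0.45)),
                predictors = c(KNOWN_BANDS, catBuilt)),
      ClassSpec(5, "ecosystem_complex",
                list(spectralRule("R65", ">", 0.8)),
                phase2 = list(spatialRule("within_buffer", "shoreline",
                                          radius = params$shoreBufferM)),
                predictors = c(KNOWN_BANDS, catRatio)),
      ClassSpec(6, "woody_crops",
                list(spectralRule("R65", ">", 0.6)),
                phase2 = list(spatialRule("within_polygons", "concessions")),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(7, "grasslands",
                list(spectralRule("R65", ">", 0.8),
                     spectralRule("NDVI", "<", 0.4)),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(8, "tree_cover_dense",
                list(spectralRule("B6", ">", 0.14)),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(9, "tree_cover_open",
                list(spectralRule("B5", ">", 0.28)),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(10, "mixed_vegetation",
                predictors = c(KNOWN_BANDS, catVeg, catRatio)))
    order <- c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 9L, 10L, 7L)
    floodCodes <- integer()
    window <- list(style = "seasonal", season = "dry", centerYear = 2015L)
  } else {
    legend <- gabonLegend()
    specs <- list(
      ClassSpec(1, "water", list(spectralRule("MNDWI", ">", -0.23)),
                predictors = c(KNOWN_BANDS, catWater), verify = slopeVerify),
      ClassSpec(2, "mangroves_wetlands",
                list(spectralRule("MNDWI", ">", -0.3),
                     spectralRule("NDVI", ">", 0.35)),
                phase2 = list(spatialRule("elevation_below", "dem",
                                          cap = params$demCapM)),
                predictors = c(KNOWN_BANDS, catWater, catVeg),
                verify = slopeVerify),
      ClassSpec(3, "artificial_surfaces",
                list(spectralRule("UI", ">", -0.568)),
                phase2 = list(spatialRule("within_buffer", "settlements",
                                          radius = params$settlementBufferM)),
                predictors = c(KNOWN_BANDS, catBuilt)),
      ClassSpec(4, "barren_land",
                list(spectralRule("UI", ">", -0.568)),
                phase2 = list(spatialRule("after_class_removed",
                                          class = "artificial_surfaces")),
                predictors = c(KNOWN_BANDS, catBuilt)),
      ClassSpec(5, "woody_crops",
                list(spectralRule("R65", ">", 0.6)),
                phase2 = list(spatialRule("within_polygons", "concessions")),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(6, "grasslands",
                list(spectralRule("R65", ">", 0.59),
                     spectralRule("NDVI", "<", 0.45)),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(7, "tree_cover_dense",
                phase2 = list(spatialRule("within_polygons", "forest_extent")),
                predictors = c(KNOWN_BANDS, catVeg, catRatio)),
      ClassSpec(8, "tree_cover_open",
                predictors = c(KNOWN_BANDS, catVeg, catRatio)))
    order <- c(1L, 2L, 3L, 4L, 5L, 9L, 10L, 7L, 8L, 6L)
    floodCodes <- c(seasonal = 9L, permanent = 10L)
    window <- list(style = "annual", centerYear = 2015L)
  }
  names(specs) <- vapply(specs, function(s) s@name, "")
  new("PipelineConfig", country = country, legend = legend, specs = specs,
      order = order, floodCodes = floodCodes, trees = 100L,
      nPerClassValidation = 50L, seed = as.integer(seed),
      qaDialect = list(cloud = 0L, shadow = 1L, fill = 2L),
      window = window, params = params)
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig '%s': %d classes, %d trees, seed %d\n",
              object@country, nrow(object@legend@entries), object@trees,
              object@seed))
  cat("  classification order:",
      paste(nameForCode(object@legend, object@order), collapse = " > "), "\n")
  if (length(object@floodCodes))
    cat("  SAR flood codes:", paste(names(object@floodCodes),
        object@floodCodes, sep = "=", collapse = ", "), "\n")
})

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields take the country profile's documented defaults. The
#' file may set `profile`, `seed`, `trees`, `n_validation_per_class`,
#' `qa_dialect`, `window`, any scalar under `params`, and per-class rule
#' overrides under `classes: <name>: phase1: [{layer, comparator,
#' threshold}]`. A rule citing an unknown band/index is a configuration
#' error. The fully resolved configuration is echoed to the log.
#'
#' @param path YAML file path.
#' @return a [PipelineConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "liberia"
  if (!profile %in% c("liberia", "gabon"))
    stop(sprintf("unknown profile '%s'", profile))
  cfg <- countryProfile(profile, seed = as.integer(y$seed %||% 1L))
  if (!is.null(y$trees)) cfg@trees <- as.integer(y$trees)
  if (!is.null(y$n_validation_per_class))
    cfg@nPerClassValidation <- as.integer(y$n_validation_per_class)
  if (!is.null(y$qa_dialect))
    cfg@qaDialect <- utils::modifyList(cfg@qaDialect,
                                       lapply(y$qa_dialect, as.integer))
  if (!is.null(y$window)) cfg@window <- utils::modifyList(cfg@window, y$window)
  if (!is.null(y$params)) cfg@params <- utils::modifyList(cfg@params, y$params)
  for (cl in names(y$classes %||% list())) {
    if (!cl %in% names(cfg@specs))
      stop(sprintf("config refers to unknown class '%s'", cl))
    ov <- y$classes[[cl]]
    if (!is.null(ov$phase1))
      cfg@specs[[cl]]@phase1 <- lapply(ov$phase1, function(r)
        spectralRule(r$layer, r$comparator %||% ">", r$threshold))
    if (!is.null(ov$predictors))
      cfg@specs[[cl]]@predictors <- {
        bad <- setdiff(ov$predictors, c(KNOWN_BANDS, KNOWN_INDICES))
        if (length(bad)) stop(sprintf("unknown predictor layer(s): %s",
                                      paste(bad, collapse = ", ")))
        unlist(ov$predictors)
      }
  }
  validObject(cfg)
  scInfo("resolved config: profile=%s seed=%d trees=%d classes=%s",
         cfg@country, cfg@seed, cfg@trees,
         paste(names(cfg@specs), collapse = ","))
  cfg
}
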