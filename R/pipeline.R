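#' @include accuracy.R
NULL

#' Run the full mapping pipeline
#'
#' Chains every stage: QA cloud masking of each scene, window selection,
#' median compositing, spectral indices, SAR flood detection (when a SAR
#' pair is supplied and the profile has flood codes), sequential binary
#' random-forest classification, and - when a reference map is supplied -
#' stratified validation (error matrix, accuracy statistics) and area
#' summaries. With the same configuration, inputs and seed the run is
#' deterministic.
#'
#' @param config a [PipelineConfig-class].
#' @param scenes list of [SceneStack-class].
#' @param vectors named list of ancillary [VectorLayer-class].
#' @param dem DEM [RasterGrid-class].
#' @param training data.frame of training pixels (`row`, `col`, `name`).
#' @param sarPair optional list with `dry` and `rainy` HH rasters.
#' @param reference optional [LandCoverMap-class] used as validation truth.
#' @param outputDir optional directory: intermediates (composite, indices,
#'   flood map) and the final map are persisted there.
#' @return list: `map` ([LandCoverMap-class]), `composite`, `indices`,
#'   `floodMap` (or NULL), and `report` (NULL without a reference; otherwise
#'   `samples`, `errorMatrix`, `stats`, `areas`).
#' @export
runPipeline <- function(config, scenes, vectors, dem, training,
                        sarPair = NULL, reference = NULL, outputDir = NULL) {
  masked <- lapply(scenes, maskClouds, qaDialect = config@qaDialect)
  windowed <- selectWindow(masked, config@window)
  composite <- medianComposite(windowed)
  indices <- computeIndexStack(composite)

  floodMap <- NULL
  if (!is.null(sarPair) && length(config@floodCodes)) {
    fd <- detectFlooded(sarPair$dry, dem, demCap = config@params$floodDemCapM)
    fr <- detectFlooded(sarPair$rainy, dem, demCap = config@params$floodDemCapM)
    floodMap <- combineSeasons(fd, fr, composite@bands)
  }

  map <- runSequentialClassification(composite, indices, config, training,
                                     vectors = vectors, dem = dem,
                                     floodMap = floodMap)

  report <- NULL
  if (!is.null(reference)) {
    samples <- stratifiedSample(map, config@nPerClassValidation,
                                seed = config@seed)
    samples <- labelFromTruth(samples, reference)
    em <- buildErrorMatrix(samples, legend = config@legend)
    report <- list(samples = samples, errorMatrix = em,
                   stats = accuracyStats(em), areas = classAreas(map))
  }

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeRaster(composite@bands, file.path(outputDir, "composite"))
    writeRaster(composite@validCount, file.path(outputDir, "valid_count"))
    writeRaster(as(indices, "RasterGrid"), file.path(outputDir, "indices"))
    if (!is.null(floodMap))
      writeRaster(floodMap@grid, file.path(outputDir, "flood"))
    writeLandCoverMap(map, file.path(outputDir, "landcover"))
    if (!is.null(report)) {
      utils::write.csv(report$errorMatrix@counts,
                       file.path(outputDir, "error_matrix.csv"))
      utils::write.csv(report$areas, file.path(outputDir, "areas.csv"),
                       row.names = FALSE)
    }
  }
  list(map = map, composite = composite, indices = indices,
       floodMap = floodMap, report = report)
}

#' Simulate a landscape and run the pipeline end to end
#'
#' Convenience wrapper used by the examples and the validation scripts:
#' generates the synthetic landscape, scene collection (and SAR pair for
#' Gabon), training samples, runs [runPipeline()] against the generator's
#' truth, and returns its result plus the generator outputs.
#'
#' @param country `"liberia"` or `"gabon"`.
#' @param seed integer seed driving every random stage.
#' @param nrow,ncol grid size (default 200).
#' @param cloudFraction per-date cloud fraction (default 0).
#' @param noiseScale multiplier on library noise SDs (default 1).
#' @return the [runPipeline()] result, plus `landscape`, `truth` and
#'   `overallVsTruth` (whole-map agreement with the generator's labels).
#' @export
runSyntheticPipeline <- function(country = c("liberia", "gabon"), seed = 1L,
                                 nrow = 200L, ncol = 200L,
                                 cloudFraction = 0, noiseScale = 1) {
  country <- match.arg(country)
  config <- countryProfile(country, seed = seed)
  landscape <- generateLandscape(country, nrow = nrow, ncol = ncol)
  library <- defaultSpectralLibrary(country)
  scenes <- generateScenes(landscape, library, defaultSceneDates(country),
                           cloudFraction = cloudFraction, seed = seed,
                           noiseScale = noiseScale)
  training <- sampleTraining(landscape$truth, nPerClass = 500L, seed = seed)
  sarPair <- if (country == "gabon")
    generateSARPair(landscape, seed = seed) else NULL
  res <- runPipeline(config, scenes, landscape$vectors, landscape$dem,
                     training, sarPair = sarPair,
                     reference = landscape$truth)
  truthV <- gridValues(landscape$truth@grid, 1L)
  mapV <- gridValues(res$map@grid, 1L)
  ok <- !is.na(mapV) & !is.na(truthV)
  res$landscape <- landscape
  res$truth <- landscape$truth
  res$overallVsTruth <- mean(mapV[ok] == truthV[ok])
  res
}
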