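options(SeqCover.logLevel = "quiet")

# tiny single/multi-band grid builders used across the suite
tinyGrid <- function(..., pixelSize = 30) {
  mats <- list(...)
  arr <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
  RasterGrid(arr, bandNames = names(mats), pixelSize = pixelSize)
}

# a one-scene SceneStack from named band matrices and an optional QA matrix
makeScene <- function(bands, qa = NULL, date = as.Date("2015-01-15"),
                      season = "dry") {
  g <- do.call(tinyGrid, bands)
  if (is.null(qa)) qa <- matrix(0L, dim(g)[1], dim(g)[2])
  new("SceneStack", bands = g, qa = SeqCover:::gridLike(g, qa, "QA"),
      date = date, season = season)
}

# composite with given band matrices (single scene, no clouds)
makeComposite <- function(bands) {
  medianComposite(list(makeScene(bands)))
}

# uniform-value band matrices over an n x n grid
constBands <- function(vals, n = 4) {
  lapply(vals, function(v) matrix(v, n, n))
}

# small deterministic land-cover map with the given code matrix
makeMap <- function(codes, legend) {
  new("LandCoverMap",
      grid = RasterGrid(matrix(as.integer(codes), nrow(codes), ncol(codes)),
                        bandNames = "code"),
      legend = legend)
}

# cached small end-to-end runs shared by pipeline + acceptance tests
e2eRun <- local({
  cache <- list()
  function(country, seed = 1L, nrow = 200L, ncol = 200L) {
    key <- paste(country, seed, nrow, ncol)
    if (is.null(cache[[key]]))
      cache[[key]] <<- runSyntheticPipeline(country, seed = seed,
                                            nrow = nrow, ncol = ncol)
    cache[[key]]
  }
})
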