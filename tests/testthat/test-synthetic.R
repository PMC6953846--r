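test_that("generated truth maps place every legend class with sane geometry", {
  for (country in c("liberia", "gabon")) {
    ls <- generateLandscape(country, nrow = 120, ncol = 120)
    truth <- gridValues(ls$truth@grid, 1)
    expect_setequal(unique(as.vector(truth)), legendCodes(ls$legend))
    dem <- gridValues(ls$dem, 1)
    mg <- truth == SeqCover:::codeForName(ls$legend, "mangroves_wetlands")
    expect_true(all(dem[mg] < 95))
    wc <- truth == SeqCover:::codeForName(ls$legend, "woody_crops")
    inside <- rasterizeLayer(ls$vectors$concessions, ls$dem)
    expect_true(all(inside[wc]))
  }
})

test_that("flooded-forest strips lie in the low-DEM river corridor", {
  ls <- generateLandscape("gabon", nrow = 120, ncol = 120)
  truth <- gridValues(ls$truth@grid, 1)
  dem <- gridValues(ls$dem, 1)
  fl <- truth %in% SeqCover:::codeForName(ls$legend, "flooded_forest_seasonal") |
    truth %in% SeqCover:::codeForName(ls$legend, "flooded_forest_permanent")
  expect_true(all(dem[fl] < 60))
})

test_that("a too-small grid refuses to place all classes", {
  expect_error(generateLandscape("liberia", nrow = 30, ncol = 30),
               "too small")
})

test_that("zero-noise scenes reproduce library means exactly", {
  ls <- generateLandscape("liberia", nrow = 80, ncol = 80)
  lib <- defaultSpectralLibrary("liberia")
  sc <- generateScenes(ls, lib, defaultSceneDates("liberia")[1, ],
                       cloudFraction = 0, seed = 1, noiseScale = 0)[[1]]
  truth <- gridValues(ls$truth@grid, 1)
  for (cl in c("water", "grasslands", "tree_cover_dense")) {
    px <- truth == SeqCover:::codeForName(ls$legend, cl)
    for (b in c("B4", "B6")) {
      vals <- gridValues(sc@bands, b)[px]
      expect_equal(unique(vals), lib@means[cl, b])
    }
  }
})

test_that("rainy scenes shift tree-class NIR by the seasonal offset", {
  ls <- generateLandscape("gabon", nrow = 80, ncol = 80)
  lib <- defaultSpectralLibrary("gabon")
  dates <- data.frame(date = as.Date(c("2015-03-01", "2015-08-10")),
                      season = c("dry", "rainy"))
  sc <- generateScenes(ls, lib, dates, seed = 3)
  truth <- gridValues(ls$truth@grid, 1)
  px <- truth == SeqCover:::codeForName(ls$legend, "tree_cover_dense")
  d <- mean(gridValues(sc[[1]]@bands, "B5")[px])
  r <- mean(gridValues(sc[[2]]@bands, "B5")[px])
  se <- lib@sds[1, "B5"] / sqrt(sum(px))
  expect_lt(abs((r - d) - 0.03), 3 * sqrt(2) * se)
})

test_that("scene generation is seed-deterministic and clouds flag QA bits", {
  ls <- generateLandscape("liberia", nrow = 80, ncol = 80)
  lib <- defaultSpectralLibrary("liberia")
  dates <- defaultSceneDates("liberia")
  a <- generateScenes(ls, lib, dates, cloudFraction = 0.2, seed = 11)
  b <- generateScenes(ls, lib, dates, cloudFraction = 0.2, seed = 11)
  expect_identical(gridValues(a[[2]]@bands), gridValues(b[[2]]@bands))
  expect_identical(gridValues(a[[2]]@qa), gridValues(b[[2]]@qa))
  qa <- gridValues(a[[1]]@qa, 1)
  expect_gt(sum(bitwAnd(as.integer(qa), 1L) != 0), 0)  # some cloud bits set
})

test_that("default library satisfies each Phase-I rule for its class and
           breaks it for at least one other", {
  for (country in c("liberia", "gabon")) {
    cfg <- countryProfile(country)
    lib <- defaultSpectralLibrary(country)
    # evaluate an index/band on a class-mean signature
    layerVal <- function(cl, layer) {
      comp <- makeComposite(constBands(as.list(lib@means[cl, ]), n = 2))
      if (layer %in% SeqCover:::KNOWN_BANDS)
        gridValues(comp@bands, layer)[1, 1]
      else gridValues(computeIndex(comp, layer), 1)[1, 1]
    }
    for (spec in cfg@specs) {
      for (rule in spec@phase1) {
        pass <- function(cl) {
          v <- layerVal(cl, rule@layer)
          if (rule@comparator == ">") v > rule@threshold else v < rule@threshold
        }
        expect_true(pass(spec@name),
                    label = sprintf("%s: %s rule holds for target", country,
                                    spec@name))
        others <- setdiff(rownames(lib@means), spec@name)
        expect_true(any(!vapply(others, pass, logical(1))),
                    label = sprintf("%s: %s rule excludes someone", country,
                                    spec@name))
      }
    }
  }
})

test_that("SAR pair raises HH over permanent strips in both seasons and
           seasonal strips only in the rainy scene", {
  ls <- generateLandscape("gabon", nrow = 100, ncol = 100)
  sar <- generateSARPair(ls, seed = 5)
  truth <- gridValues(ls$truth@grid, 1)
  perm <- truth == SeqCover:::codeForName(ls$legend, "flooded_forest_permanent")
  seas <- truth == SeqCover:::codeForName(ls$legend, "flooded_forest_seasonal")
  bg <- truth == SeqCover:::codeForName(ls$legend, "tree_cover_dense")
  for (g in sar) expect_gt(mean(gridValues(g, 1)[perm]),
                           mean(gridValues(g, 1)[bg]) + 0.15)
  expect_gt(mean(gridValues(sar$rainy, 1)[seas]),
            mean(gridValues(sar$rainy, 1)[bg]) + 0.15)
  expect_lt(abs(mean(gridValues(sar$dry, 1)[seas]) -
                mean(gridValues(sar$dry, 1)[bg])), 0.05)
})
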