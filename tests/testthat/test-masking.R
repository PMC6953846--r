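sigFixture <- function(noiseScale = 0, n = 500, seed = 2) {
  ls <- generateLandscape("liberia", nrow = 100, ncol = 100)
  lib <- defaultSpectralLibrary("liberia")
  sc <- generateScenes(ls, lib, defaultSceneDates("liberia")[1, ],
                       seed = seed, noiseScale = noiseScale)
  comp <- medianComposite(sc)
  stack <- computeIndexStack(comp)
  training <- sampleTraining(ls$truth, nPerClass = n, seed = seed)
  list(ls = ls, lib = lib, comp = comp, stack = stack, training = training)
}

test_that("signatures on zero-noise scenes equal the library exactly", {
  f <- sigFixture(noiseScale = 0)
  sig <- deriveSignatures(f$training, f$comp, f$stack)
  for (cl in c("water", "barren_land", "tree_cover_open")) {
    got <- sig$table[sig$table$class == cl & sig$table$layer == "B6", ]
    expect_equal(got$mean, f$lib@means[cl, "B6"])
    expect_equal(got$sd, 0)
  }
})

test_that("single-pixel classes get SD zero; empty classes error", {
  f <- sigFixture(noiseScale = 0)
  one <- f$training[f$training$name == "water", ][1, ]
  sig <- deriveSignatures(one, f$comp, f$stack, layers = "B6")
  expect_equal(sig$table$sd, 0)
  none <- one[0, ]
  expect_error(deriveSignatures(none, f$comp, f$stack), "sample")
})

test_that("noisy sample means land within the standard-error bound", {
  f <- sigFixture(noiseScale = 1, n = 500)
  sig <- deriveSignatures(f$training, f$comp, f$stack, layers = "B5")
  for (cl in unique(f$training$name)) {
    got <- sig$table[sig$table$class == cl & sig$table$layer == "B5", ]
    # composite of 3 scenes: median SE is close to the single-scene SE bound
    expect_lt(abs(got$mean - f$lib@means[cl, "B5"]),
              3 * f$lib@sds[1, "B5"] / sqrt(got$n))
  }
})

test_that("suggested thresholds retain all target samples, loosest side", {
  sig <- structure(list(
    table = NULL,
    values = list(a = list(MNDWI = c(0.1, 0.3, 0.5)),
                  b = list(MNDWI = c(-0.6, -0.4)))), class = "classSignatures")
  rule <- suggestThreshold(sig, "a", "MNDWI")
  expect_equal(rule@comparator, ">")
  expect_lte(rule@threshold, 0.1)
  expect_true(all(c(0.1, 0.3, 0.5) > rule@threshold))
  # direction flips when the target sits low
  rule2 <- suggestThreshold(sig, "b", "MNDWI")
  expect_equal(rule2@comparator, "<")
  expect_gte(rule2@threshold, -0.4)
})

test_that("fully separated classes are excluded by the suggested rule", {
  f <- sigFixture(noiseScale = 1, n = 400, seed = 4)
  sig <- deriveSignatures(f$training, f$comp, f$stack)
  rule <- suggestThreshold(sig, "water", "MNDWI")
  held <- sampleTraining(f$ls$truth, nPerClass = 100, seed = 99)
  mndwi <- gridValues(computeIndex(f$comp, "MNDWI"), 1)
  tc <- held[held$name == "tree_cover_dense", ]
  v <- mndwi[cbind(tc$row, tc$col)]
  expect_true(all(v <= rule@threshold))  # 100% exclusion of separated class
})

test_that("no-separation layers are flagged non-discriminative", {
  sig <- structure(list(
    table = NULL,
    values = list(a = list(BI = rep(0.2, 5)), b = list(BI = rep(0.2, 5)))),
    class = "classSignatures")
  expect_warning(rule <- suggestThreshold(sig, "a", "BI"), "no separation")
  expect_true(isTRUE(rule@params$nonDiscriminative))
})

test_that("Phase I applies printed thresholds with strict comparators", {
  comp <- makeComposite(list(B3 = matrix(c(.10, .07, .065, .1), 2, 2),
                             B6 = matrix(.10, 2, 2),
                             B4 = matrix(.1, 2, 2),
                             B5 = matrix(c(.3, .3, .3, .1), 2, 2)))
  stack <- computeIndexStack(comp, c("MNDWI", "NDVI"))
  avail <- matrix(TRUE, 2, 2)
  # MNDWI: 0.0, -0.176, -0.212, 0.0 -> water rule > -0.2 keeps all but [1,2]
  water <- applyPhase1(comp, stack, list(spectralRule("MNDWI", ">", -0.2)),
                       avail)
  expect_identical(as.vector(water), c(TRUE, TRUE, FALSE, TRUE))
  # mangroves: MNDWI > -0.35 AND NDVI > 0.3; pixel [2,2] has NDVI = 0
  mang <- applyPhase1(comp, stack,
                      list(spectralRule("MNDWI", ">", -0.35),
                           spectralRule("NDVI", ">", 0.3)), avail)
  expect_identical(as.vector(mang), c(TRUE, TRUE, TRUE, FALSE))
  # boundary equality fails a strict ">"
  eq <- applyPhase1(comp, stack, list(spectralRule("MNDWI", ">", 0.0)), avail)
  expect_false(eq[1, 1])
})

test_that("Phase I with impossible rules empties the mask", {
  comp <- makeComposite(constBands(list(B3 = .1, B6 = .1)))
  stack <- computeIndexStack(comp, "MNDWI")
  cand <- applyPhase1(comp, stack, list(spectralRule("MNDWI", ">", 2)),
                      matrix(TRUE, 4, 4))
  expect_false(any(cand))
})

test_that("Phase II enforces buffers, polygons, elevation and ordering", {
  g <- RasterGrid(matrix(0, 100, 100))  # 3 km x 3 km at 30 m
  cand <- matrix(TRUE, 100, 100)
  sett <- new("VectorLayer",
              geometries = list(SeqCover:::pixelCenters(g, 50, 10)),
              geomType = "point", kind = "settlements",
              attributes = data.frame(id = 1), crs = "local")
  out <- applyPhase2(cand, list(spatialRule("within_buffer", "settlements",
                                            radius = 600)),
                     g, vectors = list(settlements = sett))
  expect_true(out[50, 10])          # at the settlement
  expect_true(out[50, 29])          # 19 px = 570 m away
  expect_false(out[50, 80])         # 2.1 km away: outside the buffer

  shore <- new("VectorLayer",
               geometries = list(cbind(x = c(0, 0), y = c(0, 3000))),
               geomType = "line", kind = "shoreline",
               attributes = data.frame(id = 1), crs = "local")
  out <- applyPhase2(cand, list(spatialRule("within_buffer", "shoreline",
                                            radius = 1000)),
                     g, vectors = list(shoreline = shore))
  expect_true(out[50, 30])          # 885 m inland
  expect_false(out[50, 51])         # 1515 m inland: removed

  dem <- SeqCover:::gridLike(g, matrix(c(rep(10, 5000), rep(120, 5000)),
                                       100, 100), "elevation")
  out <- applyPhase2(cand, list(spatialRule("elevation_below", "dem",
                                            cap = 95)), g, dem = dem)
  expect_true(out[1, 1])
  expect_false(out[1, 100])         # DEM 120 -> removed

  expect_error(
    applyPhase2(cand, list(spatialRule("after_class_removed",
                                       class = "artificial_surfaces")), g),
    "artificial_surfaces")
  prior <- matrix(FALSE, 100, 100); prior[1, 1] <- TRUE
  out <- applyPhase2(cand, list(spatialRule("after_class_removed",
                                            class = "artificial_surfaces")),
                     g, assigned = list(artificial_surfaces = prior))
  expect_false(out[1, 1])
  expect_true(out[2, 2])

  expect_error(
    applyPhase2(cand, list(spatialRule("within_polygons", "concessions")), g),
    "concessions")
})

test_that("masking is monotone and rule-order invariant", {
  set.seed(8)
  comp <- makeComposite(list(B3 = matrix(runif(100), 10, 10),
                             B6 = matrix(runif(100), 10, 10),
                             B5 = matrix(runif(100), 10, 10)))
  stack <- computeIndexStack(comp, c("MNDWI", "NDBI"))
  avail <- matrix(TRUE, 10, 10)
  rules <- list(spectralRule("MNDWI", ">", -0.2),
                spectralRule("B6", "<", 0.8),
                spectralRule("NDBI", ">", -0.5))
  prev <- avail
  for (k in seq_along(rules)) {
    cur <- applyPhase1(comp, stack, rules[seq_len(k)], avail)
    expect_true(all(cur <= prev))   # adding a rule never grows the set
    prev <- cur
  }
  shuffled <- applyPhase1(comp, stack, rules[c(3, 1, 2)], avail)
  expect_identical(as.vector(prev), as.vector(shuffled))
})
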