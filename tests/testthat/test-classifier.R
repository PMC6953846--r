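test_that("binary RF separates well-separated clouds and is seed-stable", {
  set.seed(1)
  n <- 1000
  x <- data.frame(a = c(rnorm(n / 2, 0), rnorm(n / 2, 5)),  # 5 sigma apart
                  b = c(rnorm(n / 2, 0), rnorm(n / 2, 5)))
  y <- rep(c("class", "other"), each = n / 2)
  hold <- sample(n, 0.3 * n)
  fit <- trainBinaryRF(x[-hold, ], y[-hold], seed = 7)
  acc <- mean(predict(fit, x[hold, ]) == y[hold])
  expect_gte(acc, 0.99)

  fit2 <- trainBinaryRF(x[-hold, ], y[-hold], seed = 7)
  expect_identical(predict(fit, x[hold, ]), predict(fit2, x[hold, ]))
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(2)
  n <- 1000
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- sample(rep(c("class", "other"), each = n / 2))
  hold <- sample(n, 0.3 * n)
  fit <- trainBinaryRF(x[-hold, ], y[-hold], seed = 3)
  acc <- mean(predict(fit, x[hold, ]) == y[hold])
  expect_lt(abs(acc - 0.5), 0.06)
})

test_that("degenerate training sets are handled per contract", {
  x <- data.frame(a = rep(c(0, 5), each = 20))
  y <- rep(c("class", "other"), each = 20)
  expect_silent(fit <- trainBinaryRF(rbind(x, x), c(y, y), seed = 1))
  expect_error(trainBinaryRF(x, rep("class", 40), seed = 1), "both")
  expect_error(trainBinaryRF(x[1:25, , drop = FALSE], y[1:25], seed = 1),
               ">= 10")
})

test_that("pool propagation conserves the pixel partition", {
  avail <- matrix(TRUE, 10, 10)
  cls <- matrix(FALSE, 10, 10); cls[1:3, 1:3] <- TRUE
  out <- propagateMask(avail, cls)
  expect_equal(sum(avail) - sum(out), 9)
  expect_identical(propagateMask(avail, matrix(FALSE, 10, 10)), avail)
  expect_error(propagateMask(out, cls), "invariant breach")
})

test_that("class rasters composite into a single coded map, disjoint only", {
  leg <- liberiaLegend()
  template <- RasterGrid(matrix(0, 10, 10))
  rs <- list()
  for (i in 1:10) {
    m <- matrix(FALSE, 10, 10); m[i, ] <- TRUE
    rs[[legendNames(leg)[i]]] <- m
  }
  map <- compositeMap(rs, leg, template)
  v <- gridValues(map@grid, 1)
  expect_setequal(unique(as.vector(v)), 1:10)
  expect_equal(sum(v == 0), 0)  # ten 10-pixel rows fill the whole grid
  rs2 <- rs
  rs2[[2]][1, 1] <- TRUE        # overlaps class 1
  expect_error(compositeMap(rs2, leg, template), "disjoint")
})

test_that("slope verification reverts steep water and nothing on flat land", {
  assigned <- matrix(TRUE, 20, 20)
  flat <- RasterGrid(matrix(5, 20, 20), bandNames = "elevation")
  rules <- list(spatialRule("slope_below", cap = 10))
  out <- verifyClass(assigned, rules, flat)
  expect_equal(attr(out, "reverted"), 0)
  expect_equal(out, assigned, ignore_attr = TRUE)

  # a cliff: elevation jumps 60 m between adjacent 30 m columns (~45 deg)
  cliff <- RasterGrid(matrix(rep(c(0, 60), each = 200), 20, 20),
                      bandNames = "elevation")
  out <- verifyClass(assigned, rules, cliff)
  expect_gt(attr(out, "reverted"), 0)
  expect_false(out[10, 10])     # at the cliff edge
  expect_equal(verifyClass(assigned, list(), cliff), assigned,
               ignore_attr = TRUE)
})

test_that("Horn slope matches hand-computed gradients", {
  # plane rising 3 m per 30 m pixel eastward: slope = atan(0.1)
  plane <- RasterGrid(matrix(rep(seq(0, 57, by = 3), each = 20), 20, 20),
                      bandNames = "elevation")
  s <- gridValues(terrainSlope(plane), 1)
  expect_equal(s[10, 10], atan(0.1) * 180 / pi, tolerance = 1e-10)
  expect_equal(s[10, 10], 5.71, tolerance = 0.01)
})

test_that("classification assigns only candidate pixels", {
  f <- local({
    ls <- generateLandscape("liberia", nrow = 80, ncol = 80)
    lib <- defaultSpectralLibrary("liberia")
    sc <- generateScenes(ls, lib, defaultSceneDates("liberia"), seed = 1)
    comp <- medianComposite(lapply(sc, maskClouds))
    list(ls = ls, comp = comp, stack = computeIndexStack(comp),
         training = sampleTraining(ls$truth, 300, seed = 1))
  })
  cfg <- countryProfile("liberia")
  avail <- !gapMask(f$comp)
  spec <- cfg@specs$water
  res <- classifyClass(f$comp, f$stack, spec, avail, cfg, f$training,
                       vectors = f$ls$vectors, dem = f$ls$dem)
  cand <- applyPhase1(f$comp, f$stack, spec@phase1, avail)
  expect_true(all(res$assigned <= cand))      # never outside the mask
  truth <- gridValues(f$ls$truth@grid, 1)
  expect_true(all(truth[res$assigned] == 1))  # clean water recovery here
  # empty candidates: class skipped with a warning, nothing assigned
  expect_warning(
    res0 <- classifyClass(f$comp, f$stack, spec,
                          matrix(FALSE, 80, 80), cfg, f$training),
    "empty")
  expect_equal(sum(res0$assigned), 0)
})
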