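test_that("flood detection needs both high HH and low elevation", {
  g <- RasterGrid(matrix(0.2, 40, 40), bandNames = "HH")
  amp <- matrix(0.2, 40, 40)
  amp[5, 5] <- 0.6    # lowland, elevated HH
  amp[5, 35] <- 0.6   # upland, elevated HH
  hh <- SeqCover:::gridLike(g, amp, "HH")
  dem <- SeqCover:::gridLike(g, matrix(rep(c(10, 200), each = 800), 40, 40),
                             "elevation")
  fl <- detectFlooded(hh, dem, demCap = 60, threshold = 0.4)
  expect_true(fl[5, 5])
  expect_false(fl[5, 35])   # DEM constraint wins over backscatter
  expect_equal(sum(fl), 1)
})

test_that("auto-thresholding splits a 5-sigma mixture with <= 1% error", {
  set.seed(3)
  n <- 4000
  labels <- rep(c(FALSE, TRUE), each = n / 2)
  amp <- ifelse(labels, rnorm(n, 0.45, 0.02), rnorm(n, 0.25, 0.02))
  g <- RasterGrid(matrix(amp, 50, 80), bandNames = "HH")
  dem <- SeqCover:::gridLike(g, matrix(5, 50, 80), "elevation")
  fl <- detectFlooded(g, dem, demCap = 60, threshold = "otsu")
  err <- mean(as.vector(fl) != labels)
  expect_lte(err, 0.01)
})

test_that("otsu matches a brute-force between-class-variance search", {
  set.seed(4)
  x <- c(rnorm(500, 2, 0.3), rnorm(500, 6, 0.5))
  thr <- otsuThreshold(x, nbins = 64)
  # oracle: scan the same candidate cut points, maximize between-class var
  rng <- range(x)
  cuts <- rng[1] + seq_len(64) * diff(rng) / 64
  bcv <- vapply(cuts, function(t) {
    w0 <- mean(x <= t)
    if (w0 == 0 || w0 == 1) return(-Inf)
    w0 * (1 - w0) * (mean(x[x <= t]) - mean(x[x > t]))^2
  }, numeric(1))
  oracle <- cuts[which.max(bcv)]
  expect_lt(abs(thr - oracle), diff(rng) / 64 * 2)
  expect_true(thr > 2.5 & thr < 5.5)  # lands between the modes
})

test_that("constant amplitude demands a fixed threshold", {
  g <- RasterGrid(matrix(0.3, 10, 10), bandNames = "HH")
  dem <- SeqCover:::gridLike(g, matrix(5, 10, 10), "elevation")
  expect_error(detectFlooded(g, dem, threshold = "otsu"), "fixed threshold")
})

test_that("season combination follows the dual-season rule exhaustively", {
  template <- RasterGrid(matrix(0, 2, 2))
  dry <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  rainy <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  fm <- combineSeasons(dry, rainy, template)
  v <- gridValues(fm@grid, 1)
  expect_equal(v[1, 1], 2)   # both seasons -> permanent
  expect_equal(v[1, 2], 1)   # rainy only -> seasonal
  expect_equal(v[2, 1], 0)   # dry only -> not flooded (anomaly)
  expect_equal(v[2, 2], 0)   # neither -> not flooded
  expect_equal(fm@anomalies, 1L)
})

test_that("flood areas conserve: permanent + seasonal = total flooded", {
  set.seed(5)
  template <- RasterGrid(matrix(0, 30, 30))
  dry <- matrix(runif(900) < 0.2, 30, 30)
  rainy <- dry | matrix(runif(900) < 0.3, 30, 30)
  fm <- combineSeasons(dry, rainy, template)
  a <- classAreas(fm)
  v <- gridValues(fm@grid, 1)
  expect_equal(sum(a$km2), sum(v > 0) * 0.0009)
  expect_equal(a$km2[a$class == "permanent"] + a$km2[a$class == "seasonal"],
               sum(v > 0) * 0.0009)
})

test_that("flood masks claim pool pixels with earlier-class precedence", {
  cfg <- countryProfile("gabon")
  codes <- matrix(0L, 30, 30)
  codes[1:10, 1:10] <- 2L       # 100 permanent
  codes[11:20, 1:20] <- 1L      # 200 seasonal
  fm <- new("FloodMap", grid = RasterGrid(codes, bandNames = "flood"),
            anomalies = 0L)
  avail <- matrix(TRUE, 30, 30)
  s <- floodToClassMask(fm, cfg, avail, "seasonal")
  p <- floodToClassMask(fm, cfg, s$available, "permanent")
  expect_equal(sum(avail) - sum(p$available), 300)

  # water already claimed part of the seasonal strip: water wins
  availW <- avail; availW[11:20, 1:5] <- FALSE
  s2 <- floodToClassMask(fm, cfg, availW, "seasonal")
  expect_equal(s2$conflicts, 50L)
  expect_equal(sum(s2$mask), 150)

  # empty flood map leaves the pool unchanged
  empty <- new("FloodMap", grid = RasterGrid(matrix(0L, 30, 30),
                                             bandNames = "flood"),
               anomalies = 0L)
  e <- floodToClassMask(empty, cfg, avail, "seasonal")
  expect_identical(e$available, avail)
})
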