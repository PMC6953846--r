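test_that("stratified sampling honours strata sizes and the seed", {
  leg <- liberiaLegend()
  codes <- matrix(rep(1:10, each = 100), 100, 10)  # 100 px per class
  map <- makeMap(codes, leg)
  s <- stratifiedSample(map, 50, seed = 1)
  expect_equal(nrow(s), 500)
  expect_true(all(table(s$mapCode) == 50))
  expect_false(any(duplicated(s[, c("row", "col")])))  # without replacement
  expect_identical(stratifiedSample(map, 50, seed = 1), s)
  expect_false(identical(stratifiedSample(map, 50, seed = 2), s))

  # samples carry the map label of their own pixel
  v <- gridValues(map@grid, 1)
  expect_true(all(v[cbind(s$row, s$col)] == s$mapCode))
})

test_that("small strata are exhausted, not oversampled", {
  leg <- ClassLegend(1:2, c("a", "b"))
  codes <- matrix(1L, 10, 10); codes[1:3, 1] <- 2L   # class b: 3 pixels
  map <- makeMap(codes, leg)
  s <- stratifiedSample(map, 50, seed = 1)
  expect_equal(sum(s$mapClass == "b"), 3)
  expect_equal(sum(s$mapClass == "a"), 50)
})

test_that("error matrices tabulate reference x map counts", {
  leg <- ClassLegend(1:3, c("a", "b", "c"))
  em <- buildErrorMatrix(ref = c("a", "a", "b", "c"),
                         map = c("a", "b", "b", "c"), legend = leg)
  expect_equal(sum(em@counts), 4)
  expect_equal(em@counts["a", "b"], 1L)
  expect_equal(diag(em@counts), c(a = 1L, b = 1L, c = 1L))
  expect_error(buildErrorMatrix(ref = "z", map = "a", legend = leg),
               "outside the legend")
})

test_that("accuracy statistics match their definitions on a toy matrix", {
  em <- new("ErrorMatrix", counts = matrix(c(45L, 10L, 5L, 40L), 2, 2,
            dimnames = list(c("c1", "c2"), c("c1", "c2"))))
  st <- accuracyStats(em)
  expect_equal(st$overall, 85 / 100)
  expect_equal(st$perClass$producers[1], 45 / 50)          # 90%
  expect_equal(st$perClass$users[1], 45 / 55)              # ~81.8%
  # 2-class collapse identity: portmanteau equals overall accuracy
  expect_equal(st$perClass$portmanteau, c(0.85, 0.85))
})

test_that("perfect maps score 100% on every statistic", {
  em <- new("ErrorMatrix", counts = diag(50L, 4) |>
              (\(m) {dimnames(m) <- list(letters[1:4], letters[1:4]); m})())
  st <- accuracyStats(em)
  expect_equal(st$overall, 1)
  expect_true(all(st$perClass$users == 1))
  expect_true(all(st$perClass$producers == 1))
  expect_true(all(st$perClass$portmanteau == 1))
})

test_that("zero marginals yield undefined statistics, not zero", {
  m <- matrix(c(10L, 5L, 0L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  st <- accuracyStats(new("ErrorMatrix", counts = m))
  expect_true(is.na(st$perClass$users[2]))       # class b never mapped
  expect_false(is.na(st$perClass$producers[2]))  # but b occurs in reference
})

test_that("statistics agree with a brute-force per-sample tally", {
  set.seed(10)
  for (rep in 1:5) {
    lv <- letters[1:4]
    ref <- sample(lv, 200, replace = TRUE)
    map <- ifelse(runif(200) < 0.7, ref, sample(lv, 200, replace = TRUE))
    st <- accuracyStats(buildErrorMatrix(ref = ref, map = map,
                                         legend = ClassLegend(1:4, lv)))
    expect_equal(st$overall, mean(ref == map))
    for (i in seq_along(lv)) {
      cl <- lv[i]
      expect_equal(st$perClass$users[i],
                   sum(ref == cl & map == cl) / sum(map == cl))
      expect_equal(st$perClass$producers[i],
                   sum(ref == cl & map == cl) / sum(ref == cl))
      expect_equal(st$perClass$portmanteau[i],
                   mean((ref == cl) == (map == cl)))
    }
  }
})

test_that("accuracy statistics are permutation-equivariant in class order", {
  set.seed(11)
  lv <- c("w", "x", "y")
  ref <- sample(lv, 150, replace = TRUE)
  map <- ifelse(runif(150) < 0.8, ref, sample(lv, 150, replace = TRUE))
  a <- accuracyStats(buildErrorMatrix(ref = ref, map = map,
                                      legend = ClassLegend(1:3, lv)))
  b <- accuracyStats(buildErrorMatrix(ref = ref, map = map,
                                      legend = ClassLegend(1:3, rev(lv))))
  expect_equal(a$overall, b$overall)
  bi <- match(a$perClass$class, b$perClass$class)
  expect_equal(a$perClass$users, b$perClass$users[bi])
  expect_equal(a$perClass$portmanteau, b$perClass$portmanteau[bi])
})

test_that("Wilson intervals bracket the point estimate inside [0, 1]", {
  em <- new("ErrorMatrix", counts = matrix(c(45L, 10L, 5L, 40L), 2, 2,
            dimnames = list(c("c1", "c2"), c("c1", "c2"))))
  st <- accuracyStats(em)
  expect_true(st$overallCI[1] < st$overall & st$overall < st$overallCI[2])
  expect_true(all(st$overallCI >= 0 & st$overallCI <= 1))
  stw <- accuracyStats(em, ciMethod = "wald")
  expect_true(stw$overallCI[1] < st$overall)
  expect_false(identical(st$overallCI, stw$overallCI))
})

test_that("areas convert pixel counts exactly and compare per class", {
  leg <- ClassLegend(1:2, c("a", "b"))
  codes <- matrix(2L, 100, 100)
  codes[1:100, 1:25] <- 1L     # 2500 px a, 7500 px b
  a <- classAreas(makeMap(codes, leg))
  expect_equal(a$km2[a$class == "a"], 2500 * 0.0009)
  expect_equal(a$km2[a$class == "b"], 6.75)

  b <- data.frame(class = c("a", "b"), km2 = c(2.0, 7.0))
  cmp <- compareAreas(a, b)
  expect_equal(cmp$deltaKm2[cmp$class == "a"], 0.25)
  expect_equal(compareAreas(a, b, class = "b"), -0.25)
  expect_error(compareAreas(a, b, class = "zzz"), "absent")
})
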