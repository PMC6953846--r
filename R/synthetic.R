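#' @include config.R spatial-utils.R
NULL

#' Default per-class spectral library
#'
#' Class-mean reflectance for bands B2-B7 plus a thermal-proxy B10, with
#' within-class standard deviations and a rainy-season offset. The default
#' means are chosen so that every default Phase-I threshold rule of the
#' country profile holds for its target class's mean signature and fails for
#' at least one other class, and so that any pair of classes that must be
#' separated by the classifier (rather than by an ancillary constraint) is at
#' least 5 noise SD apart in band space at the default SD of 0.012.
#'
#' @param country `"liberia"` or `"gabon"`.
#' @param sd within-class per-band standard deviation (default 0.012).
#' @return a [SpectralLibrary-class].
#' @export
defaultSpectralLibrary <- function(country = c("liberia", "gabon"),
                                   sd = 0.012) {
  country <- match.arg(country)
  sig <- rbind(
    water               = c(.06, .08, .05, .03, .02, .01, .30),
    mangroves_wetlands  = c(.05, .06, .05, .30, .07, .03, .32),
    artificial_surfaces = c(.18, .20, .22, .25, .32, .30, .45),
    barren_land         = c(.20, .22, .26, .28, .38, .35, .48),
    ecosystem_complex   = c(.24, .25, .24, .26, .30, .28, .40),
    woody_crops         = c(.05, .07, .08, .32, .22, .12, .33),
    grasslands          = c(.10, .12, .16, .35, .30, .18, .38),
    tree_cover_dense    = c(.04, .05, .04, .28, .16, .07, .28),
    tree_cover_open     = c(.05, .06, .05, .33, .19, .09, .30),
    mixed_vegetation    = c(.07, .09, .10, .30, .22, .13, .35),
    flooded_forest_seasonal  = c(.04, .05, .045, .26, .15, .065, .29),
    flooded_forest_permanent = c(.04, .05, .045, .26, .15, .065, .29))
  colnames(sig) <- KNOWN_BANDS
  keep <- if (country == "liberia")
    c("water", "mangroves_wetlands", "artificial_surfaces", "barren_land",
      "ecosystem_complex", "woody_crops", "grasslands", "tree_cover_dense",
      "tree_cover_open", "mixed_vegetation")
  else
    c("water", "mangroves_wetlands", "artificial_surfaces", "barren_land",
      "woody_crops", "grasslands", "tree_cover_dense", "tree_cover_open",
      "flooded_forest_seasonal", "flooded_forest_permanent")
  means <- sig[keep, , drop = FALSE]
  sds <- matrix(sd, nrow(means), ncol(means), dimnames = dimnames(means))
  # rainy season: canopy NIR rises slightly for tree-dominated classes
  off <- matrix(0, nrow(means), ncol(means), dimnames = dimnames(means))
  treeish <- intersect(rownames(means),
                       c("mangroves_wetlands", "woody_crops",
                         "tree_cover_dense", "tree_cover_open",
                         "mixed_vegetation", "flooded_forest_seasonal",
                         "flooded_forest_permanent"))
  off[treeish, "B5"] <- 0.03
  new("SpectralLibrary", means = means, sds = sds, seasonalOffset = off)
}

setMethod("show", "SpectralLibrary", function(object) {
  cat(sprintf("SpectralLibrary: %d classes x %d bands (noise SD %.3g)\n",
              nrow(object@means), ncol(object@means), object@sds[1, 1]))
  print(round(object@means, 3))
})

rectPoly <- function(grid, r0, r1, c0, c1) {
  px <- grid@pixelSize
  x0 <- grid@xmin + (c0 - 1) * px; x1 <- grid@xmin + c1 * px
  y0 <- grid@ymax - r1 * px;       y1 <- grid@ymax - (r0 - 1) * px
  m <- cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
  m
}

#' Generate a synthetic landscape: truth map, DEM and ancillary layers
#'
#' Lays out the country profile's classes on a grid with geometry consistent
#' with their semantics: an ocean strip along the western shore, a shoreline
#' line feature, mangroves and (Liberia) a sand/intertidal strip near shore
#' at low elevation, artificial-surface patches centred on generated
#' settlement points, woody-crop patches inside concession polygons, a river
#' crossing the interior whose low-lying corridor hosts (Gabon) seasonal and
#' permanent flooded-forest strips, and a dense tree-cover background. The
#' DEM rises inland at 0.8 m per pixel (mild slopes everywhere) and is
#' lowered along the river corridor.
#'
#' @param country `"liberia"` or `"gabon"`.
#' @param nrow,ncol grid size in pixels (>= 60 each; default 200).
#' @param pixelSize pixel edge, metres.
#' @param minClassPixels minimum pixels required per class (error if the
#'   layout cannot honour it).
#' @return list with `truth` ([LandCoverMap-class]), `dem`
#'   ([RasterGrid-class]), `vectors` (named list of [VectorLayer-class]:
#'   `settlements`, `concessions`, `shoreline`, plus `forest_extent` for
#'   Gabon), and `legend`.
#' @export
generateLandscape <- function(country = c("liberia", "gabon"), nrow = 200L,
                              ncol = 200L, pixelSize = 30,
                              minClassPixels = 60L) {
  country <- match.arg(country)
  if (nrow < 60L || ncol < 60L)
    stop("grid too small to place all classes (need >= 60 x 60)")
  legend <- if (country == "liberia") liberiaLegend() else gabonLegend()
  code <- function(nm) codeForName(legend, nm)
  H <- nrow; W <- ncol
  truth <- matrix(code("tree_cover_dense"), H, W)

  ow <- max(8L, round(0.08 * W))                     # ocean strip
  truth[, seq_len(ow)] <- code("water")
  rr <- round(0.5 * H)                               # river row
  truth[(rr - 1):(rr + 1), ] <- code("water")

  if (country == "liberia")                          # sand/intertidal strip
    truth[, (ow + 1):(ow + 6)] <- code("ecosystem_complex")

  mg <- list(r = round(0.62 * H):round(0.80 * H),    # mangroves near shore
             c = (ow + 7):(ow + 18))
  truth[mg$r, mg$c] <- code("mangroves_wetlands")

  grs <- list(r = round(0.05 * H):round(0.20 * H), c = round(0.60 * W):round(0.80 * W))
  truth[grs$r, grs$c] <- code("grasslands")
  brn <- list(r = round(0.05 * H):round(0.18 * H), c = round(0.30 * W):round(0.45 * W))
  truth[brn$r, brn$c] <- code("barren_land")
  opn <- list(r = round(0.30 * H):round(0.42 * H), c = round(0.55 * W):round(0.70 * W))
  truth[opn$r, opn$c] <- code("tree_cover_open")
  if (country == "liberia") {
    mx <- list(r = round(0.62 * H):round(0.74 * H), c = round(0.55 * W):round(0.70 * W))
    truth[mx$r, mx$c] <- code("mixed_vegetation")
  }

  dummy <- RasterGrid(truth, bandNames = "code", pixelSize = pixelSize)

  # settlements + artificial disks (radius 6 px around each point)
  sett <- rbind(c(round(0.25 * H), round(0.55 * W)),
                c(round(0.72 * H), round(0.85 * W)))
  for (k in seq_len(nrow(sett))) {
    rs <- pmax(1L, sett[k, 1] - 8L):pmin(H, sett[k, 1] + 8L)
    cs <- pmax(1L, sett[k, 2] - 8L):pmin(W, sett[k, 2] + 8L)
    for (r in rs) for (cl in cs)
      if ((r - sett[k, 1])^2 + (cl - sett[k, 2])^2 <= 36)
        truth[r, cl] <- code("artificial_surfaces")
  }
  settXY <- pixelCenters(dummy, sett[, 1], sett[, 2])
  settlements <- new("VectorLayer",
    geometries = lapply(seq_len(nrow(settXY)), function(i)
      matrix(settXY[i, ], 1, 2, dimnames = list(NULL, c("x", "y")))),
    geomType = "point", kind = "settlements",
    attributes = data.frame(id = seq_len(nrow(settXY))), crs = dummy@crs)

  # concession polygon containing the woody-crop patch (2 px margin)
  cn <- list(r = round(0.80 * H):round(0.95 * H), c = round(0.30 * W):round(0.50 * W))
  wc <- list(r = (min(cn$r) + 2L):(max(cn$r) - 2L),
             c = (min(cn$c) + 2L):(max(cn$c) - 2L))
  truth[wc$r, wc$c] <- code("woody_crops")
  concessions <- new("VectorLayer",
    geometries = list(rectPoly(dummy, min(cn$r), max(cn$r), min(cn$c), max(cn$c))),
    geomType = "polygon", kind = "concessions",
    attributes = data.frame(id = 1L), crs = dummy@crs)

  if (country == "gabon") {                          # flood strips flank river
    fl <- (rr + 2):(rr + 4); fu <- (rr - 4):(rr - 2)
    cP <- round(0.35 * W):round(0.60 * W)
    cS <- (round(0.60 * W) + 1L):round(0.85 * W)
    truth[c(fl, fu), cP] <- code("flooded_forest_permanent")
    truth[c(fl, fu), cS] <- code("flooded_forest_seasonal")
  }

  # DEM: rises inland, lowered within the river corridor; low where mangroves
  distShore <- matrix(rep(pmax(0L, seq_len(W) - ow), each = H), H, W)
  dem <- 0.8 * distShore
  corridor <- abs(row(dem) - rr) <= 4
  dem[corridor] <- dem[corridor] * 0.25
  demGrid <- gridLike(dummy, dem, "elevation")

  shoreX <- dummy@xmin + ow * pixelSize
  shoreline <- new("VectorLayer",
    geometries = list(cbind(x = c(shoreX, shoreX),
                            y = c(dummy@ymax - H * pixelSize, dummy@ymax))),
    geomType = "line", kind = "shoreline",
    attributes = data.frame(id = 1L), crs = dummy@crs)

  vectors <- list(settlements = settlements, concessions = concessions,
                  shoreline = shoreline)
  if (country == "gabon")
    vectors$forest_extent <- new("VectorLayer",
      geometries = list(rectPoly(dummy, 1L, H, 1L, W)),
      geomType = "polygon", kind = "forest_extent",
      attributes = data.frame(id = 1L), crs = dummy@crs)

  counts <- table(factor(truth, levels = legendCodes(legend)))
  if (any(counts < minClassPixels))
    stop(sprintf("grid too small: class '%s' has %d < %d pixels",
                 nameForCode(legend, as.integer(names(which.min(counts)))),
                 min(counts), minClassPixels))

  truthMap <- new("LandCoverMap",
                  grid = gridLike(dummy, truth, "code"), legend = legend,
                  provenance = list(source = "synthetic", country = country))
  list(truth = truthMap, dem = demGrid, vectors = vectors, legend = legend)
}

#' Generate a multi-date synthetic scene collection
#'
#' Per-pixel reflectance is the class mean (plus the rainy-season offset when
#' the scene is rainy) plus independent Gaussian band noise truncated to
#' [0, 1]. Clouds are painted as bright random disks with the QA cloud bit
#' set and a paired dark shadow disk (shadow bit) offset to the south-east.
#'
#' @param landscape output of [generateLandscape()].
#' @param library a [SpectralLibrary-class] covering all truth classes.
#' @param dates data.frame with columns `date` (Date) and `season`
#'   (`"dry"`/`"rainy"`); see [defaultSceneDates()].
#' @param cloudFraction numeric in [0, 1], recycled per date.
#' @param seed integer seed (generator is seed-deterministic).
#' @param noiseScale multiplier on the library SDs (0 = noise-free).
#' @return list of [SceneStack-class].
#' @export
generateScenes <- function(landscape, library, dates,
                           cloudFraction = 0, seed = 1L, noiseScale = 1) {
  truth <- gridValues(landscape$truth@grid, 1L)
  legend <- landscape$legend
  missing <- setdiff(legendNames(legend), rownames(library@means))
  if (length(missing))
    stop(sprintf("spectral library lacks classes: %s",
                 paste(missing, collapse = ", ")))
  cloudFraction <- rep_len(cloudFraction, nrow(dates))
  if (any(cloudFraction < 0 | cloudFraction > 1))
    stop("cloud fraction must lie in [0, 1]")
  H <- nrow(truth); W <- ncol(truth)
  classIdx <- match(nameForCode(legend, as.vector(truth)),
                    rownames(library@means))
  set.seed(as.integer(seed))
  lapply(seq_len(nrow(dates)), function(i) {
    season <- dates$season[i]
    mu <- library@means
    if (season == "rainy") mu <- mu + library@seasonalOffset
    vals <- array(NA_real_, c(H, W, length(KNOWN_BANDS)))
    for (b in seq_along(KNOWN_BANDS)) {
      v <- mu[classIdx, KNOWN_BANDS[b]] +
        stats::rnorm(H * W, 0, noiseScale * library@sds[1, b])
      vals[, , b] <- pmin(1, pmax(0, v))
    }
    qa <- matrix(0L, H, W)
    if (cloudFraction[i] > 0) {
      covered <- 0L; target <- cloudFraction[i] * H * W
      guard <- 0L
      while (covered < target && guard < 500L) {
        guard <- guard + 1L
        cr <- sample.int(H, 1L); cc <- sample.int(W, 1L)
        rad <- stats::runif(1, 4, max(5, round(0.08 * min(H, W))))
        rs <- pmax(1L, floor(cr - rad)):pmin(H, ceiling(cr + rad))
        cs <- pmax(1L, floor(cc - rad)):pmin(W, ceiling(cc + rad))
        disk <- outer(rs, cs, function(r, cl) (r - cr)^2 + (cl - cc)^2 <= rad^2)
        newpix <- sum(disk & qa[rs, cs] == 0L)
        qa[rs, cs][disk] <- bitwOr(qa[rs, cs][disk], 1L)      # cloud bit 0
        for (b in seq_along(KNOWN_BANDS)) {
          m <- vals[rs, cs, b]; m[disk] <- 0.85; vals[rs, cs, b] <- m
        }
        srs <- pmin(H, rs + 5L); scs <- pmin(W, cs + 5L)      # shadow offset
        qa[srs, scs][disk] <- bitwOr(qa[srs, scs][disk], 2L)  # shadow bit 1
        for (b in seq_along(KNOWN_BANDS)) {
          m <- vals[srs, scs, b]; m[disk] <- 0.03; vals[srs, scs, b] <- m
        }
        covered <- covered + newpix
      }
    }
    bands <- RasterGrid(vals, bandNames = KNOWN_BANDS,
                        pixelSize = landscape$dem@pixelSize)
    new("SceneStack", bands = bands,
        qa = gridLike(bands, qa, "QA"),
        date = as.Date(dates$date[i]), season = season)
  })
}

#' Default acquisition dates for a country profile
#'
#' Liberia: one scene per dry-season window (December of the year to March of
#' the following year) for the season-years around 2015. Gabon: two scenes
#' (dry and rainy) per year 2014-2016.
#'
#' @param country `"liberia"` or `"gabon"`.
#' @return data.frame with columns `date`, `season`.
#' @export
defaultSceneDates <- function(country = c("liberia", "gabon")) {
  country <- match.arg(country)
  if (country == "liberia")
    data.frame(date = as.Date(c("2015-01-15", "2016-01-15", "2017-01-15")),
               season = "dry")
  else
    data.frame(date = as.Date(c("2014-03-01", "2014-08-10", "2015-03-01",
                                "2015-08-10", "2016-03-01", "2016-08-10")),
               season = rep(c("dry", "rainy"), 3))
}

#' Generate a dual-season SAR HH amplitude pair
#'
#' Background amplitude is Gaussian around `background`; truth pixels of the
#' permanent flooded-forest class are raised by `contrast` in both seasons,
#' seasonal ones only in the rainy scene. Flood strips lie in the low-DEM
#' river corridor by construction of [generateLandscape()].
#'
#' @param landscape output of [generateLandscape()] (Gabon profile).
#' @param background mean non-flooded amplitude (linear units, default 0.25).
#' @param contrast amplitude increase over flooded forest (default 0.20).
#' @param noiseSd additive Gaussian noise SD (default 0.015).
#' @param seed integer seed.
#' @return list with `dry` and `rainy` [RasterGrid-class] HH rasters.
#' @export
generateSARPair <- function(landscape, background = 0.25, contrast = 0.20,
                            noiseSd = 0.015, seed = 1L) {
  truth <- gridValues(landscape$truth@grid, 1L)
  legend <- landscape$legend
  nm <- legendNames(legend)
  if (!all(c("flooded_forest_seasonal", "flooded_forest_permanent") %in% nm))
    stop("landscape has no flooded-forest classes; use the gabon profile")
  perm <- truth == codeForName(legend, "flooded_forest_permanent")
  seas <- truth == codeForName(legend, "flooded_forest_seasonal")
  H <- nrow(truth); W <- ncol(truth)
  set.seed(as.integer(seed))
  mk <- function(flooded) {
    amp <- matrix(background, H, W)
    amp[flooded] <- background + contrast
    amp <- amp + stats::rnorm(H * W, 0, noiseSd)
    gridLike(landscape$dem, pmax(amp, 0), "HH")
  }
  list(dry = mk(perm), rainy = mk(perm | seas))
}

#' Stratified training samples from a truth map
#'
#' Samples up to `nPerClass` pixels per legend class, uniformly without
#' replacement within each class, as the package's synthetic stand-in for
#' training polygons digitised from high-resolution imagery.
#'
#' @param truth a [LandCoverMap-class].
#' @param nPerClass samples per class (default 500).
#' @param seed integer seed.
#' @return data.frame with columns `row`, `col`, `code`, `name`.
#' @export
sampleTraining <- function(truth, nPerClass = 500L, seed = 1L) {
  v <- gridValues(truth@grid, 1L)
  set.seed(as.integer(seed))
  out <- lapply(legendCodes(truth@legend), function(code) {
    idx <- which(v == code)
    if (!length(idx)) return(NULL)
    take <- sample(idx, min(nPerClass, length(idx)))
    data.frame(row = ((take - 1L) %% nrow(v)) + 1L,
               col = ((take - 1L) %/% nrow(v)) + 1L,
               code = code, name = nameForCode(truth@legend, code))
  })
  do.call(rbind, out)
}
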