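#' @include AllClasses.R AllGenerics.R
NULL

#' Build a class legend
#'
#' @param code integer class codes (>= 1; 0 is reserved for unclassified).
#' @param name class names.
#' @param color hex colors.
#' @param applicability free-form country tag per class.
#' @return a [ClassLegend-class].
#' @export
ClassLegend <- function(code, name, color = NULL, applicability = "all") {
  if (is.null(color))
    color <- grDevices::hcl.colors(length(code), "Dark 3")
  new("ClassLegend", entries = data.frame(
    code = as.integer(code), name = as.character(name),
    color = color, applicability = rep_len(applicability, length(code)),
    stringsAsFactors = FALSE))
}

#' @rdname legendCodes
setMethod("legendCodes", "ClassLegend", function(x) x@entries$code)

#' @rdname legendCodes
setMethod("legendNames", "ClassLegend", function(x) x@entries$name)

#' @rdname legendCodes
setMethod("legendColors", "ClassLegend", function(x)
  stats::setNames(x@entries$color, x@entries$code))

#' @rdname legendCodes
setMethod("legendCodes", "LandCoverMap", function(x) legendCodes(x@legend))

#' @rdname legendCodes
setMethod("legendNames", "LandCoverMap", function(x) legendNames(x@legend))

setMethod("show", "ClassLegend", function(object) {
  cat(sprintf("ClassLegend with %d classes:\n", nrow(object@entries)))
  print(object@entries, row.names = FALSE)
})

codeForName <- function(legend, name) {
  i <- match(name, legend@entries$name)
  if (is.na(i)) stop(sprintf("unknown class name '%s'", name))
  legend@entries$code[i]
}

nameForCode <- function(legend, code) {
  i <- match(code, legend@entries$code)
  ifelse(is.na(i), "unclassified", legend@entries$name[i])
}

#' Default 10-class legends
#'
#' The two country profiles share nine thematic classes; the tenth slot is
#' Ecosystem Complex + Mixed Vegetation (Liberia) versus the two
#' flooded-forest classes (Gabon, seasonal and permanent, collapsible to one
#' class for assessment).
#'
#' @return a [ClassLegend-class].
#' @aliases gabonLegend
#' @export
liberiaLegend <- function() {
  ClassLegend(
    code = 1:10,
    name = c("water", "mangroves_wetlands", "artificial_surfaces",
             "barren_land", "ecosystem_complex", "woody_crops",
             "grasslands", "tree_cover_dense", "tree_cover_open",
             "mixed_vegetation"),
    color = c("#3066BE", "#7B2D8B", "#D7263D", "#C9B79C", "#F6E27F",
              "#8FB339", "#DDE26A", "#0B6E4F", "#4DA167", "#A4C3B2"),
    applicability = "liberia")
}

#' @rdname liberiaLegend
#' @export
gabonLegend <- function() {
  ClassLegend(
    code = 1:10,
    name = c("water", "mangroves_wetlands", "artificial_surfaces",
             "barren_land", "woody_crops", "grasslands",
             "tree_cover_dense", "tree_cover_open",
             "flooded_forest_seasonal", "flooded_forest_permanent"),
    color = c("#3066BE", "#7B2D8B", "#D7263D", "#C9B79C", "#8FB339",
              "#DDE26A", "#0B6E4F", "#4DA167", "#41B6C4", "#225EA8"),
    applicability = "gabon")
}
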