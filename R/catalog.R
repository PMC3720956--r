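#' Abiotic variable catalog
#'
#' Builds the registry of abiotic predictor variables used throughout the
#' package: percentage-cover variables measured at three nested quadrat
#' scales (25x25 cm, 50x50 cm, 1x1 m), vegetation-resistance and soil
#' variables measured on the 1x1 m quadrat, and habitat-structure variables
#' measured in 3 m and 6 m radii around the sampling point.
#'
#' Variables that are measured at several scales share a `scale_group`;
#' during predictor screening only the best-supported scale of a group is
#' retained (scale competition). Single-scale variables have
#' `scale_group = NA`.
#'
#' @return A data.frame with one row per column name that can appear in an
#'   observation table: `name`, `category` (COVER, RESISTANCE, SOIL,
#'   STRUCTURE), `scale` (25cm, 50cm, 1m, 3m, 6m), `scale_group`, `kind`
#'   (percent, length, count, ordinal, ph) and `unit`.
#' @examples
#' cat <- variable_catalog()
#' table(cat$category)
#' @export
variable_catalog <- function() {
  cover_base <- c("BARESOIL", "CALLUNA", "DUNG", "GRAMINOID", "HERB",
                  "LICHEN", "LITTER", "MOSS", "ROOT", "SEDUM", "SHRUB",
                  "STONE", "VACCINIUM", "WOOD")
  cover <- data.frame(
    name = c(paste0(cover_base, "_25"), paste0(cover_base, "_50"),
             paste0(cover_base, "_1")),
    category = "COVER",
    scale = rep(c("25cm", "50cm", "1m"), each = length(cover_base)),
    scale_group = rep(cover_base, 3),
    kind = "percent", unit = "%",
    stringsAsFactors = FALSE)

  resistance <- data.frame(
    name = c("COVER_N", "COVER_E", "COVER_S", "COVER_W", "HEIGHT",
             "SQUARE_N", "SQUARE_E", "SQUARE_S", "SQUARE_W"),
    category = "RESISTANCE", scale = "1m", scale_group = NA_character_,
    kind = c(rep("percent", 4), "length", rep("count", 4)),
    unit = c(rep("%", 4), "cm", rep("", 4)),
    stringsAsFactors = FALSE)

  soil <- data.frame(
    name = c("LITTER_DEPTH", "SOIL_0.063", "SOIL_0.125", "SOIL_0.25",
             "SOIL_0.50", "SOIL_1", "SOIL_2", "SOIL_HUMID", "SOIL_OM",
             "SOIL_PH"),
    category = "SOIL", scale = "1m", scale_group = NA_character_,
    kind = c("length", rep("percent", 6), "percent", "percent", "ph"),
    unit = c("cm", rep("%", 8), ""),
    stringsAsFactors = FALSE)

  structure <- data.frame(
    name = c("OPEN_3", "OPEN_6", "SHRUB_3", "SHRUB_6",
             "STRUCTURE_3", "STRUCTURE_6", "DIST_OPEN", "DIST_SHRUB"),
    category = "STRUCTURE",
    scale = c("3m", "6m", "3m", "6m", "3m", "6m", "6m", "6m"),
    scale_group = c("OPEN", "OPEN", "SHRUB_N", "SHRUB_N",
                    "STRUCTURE", "STRUCTURE", NA, NA),
    kind = c("count", "count", "count", "count", "ordinal", "ordinal",
             "length", "length"),
    unit = c("", "", "", "", "", "", "cm", "cm"),
    stringsAsFactors = FALSE)

  rbind(cover, resistance, soil, structure)
}

#' Map variable names to their category
#'
#' @param names character vector of variable names.
#' @param catalog a catalog as returned by [variable_catalog()].
#' @return named character vector of categories.
#' @export
variable_categories <- function(names, catalog = variable_catalog()) {
  idx <- match(names, catalog$name)
  if (anyNA(idx)) {
    stop("unknown variables: ", paste(names[is.na(idx)], collapse = ", "))
  }
  stats::setNames(catalog$category[idx], names)
}
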