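#' Survey design specification
#'
#' Describes the field-survey layout emulated by the synthetic generator:
#' two locations, each with 120 stratified-random sampling points spaced at
#' least 5.5 m apart, a 4x4 grid of 25x25 cm cells nested in the 1x1 m
#' quadrat at every point, and the rules selecting the fine-scale subset of
#' points (a minimum-larvae threshold and a cap on the number of retained
#' points, both per location).
#'
#' @param n_locations number of survey locations.
#' @param n_points_per_location sampling points placed in each location.
#' @param habitat_types named list, one element per location, each a named
#'   numeric vector of habitat allocation proportions (must sum to 1).
#' @param min_point_spacing minimum distance between points, metres.
#' @param area_side side length of the square survey extent per location,
#'   metres. Defaults approximate 9 and 15 ha.
#' @param quadrat_grid cells per side of the 1x1 m quadrat; fixed at 4 so
#'   that every point carries 16 25x25 cm cells.
#' @param min_larvae_threshold per-location minimum number of mapped larvae
#'   a point needs to enter the fine-scale data sets.
#' @param fine_scale_points_cap per-location maximum number of points kept
#'   in the fine-scale data sets (the points with the most larvae).
#' @return An object of class `survey_design`.
#' @examples
#' d <- survey_design()
#' d$n_points_per_location
#' @export
survey_design <- function(n_locations = 2L,
                          n_points_per_location = 120L,
                          habitat_types = NULL,
                          min_point_spacing = 5.5,
                          area_side = c(300, 390),
                          quadrat_grid = 4L,
                          min_larvae_threshold = c(5L, 3L),
                          fine_scale_points_cap = c(10L, 11L)) {
  if (is.null(habitat_types)) {
    habitat_types <- list(
      A = c(BARE_CUSHION = 0.30, BARE_SPOT = 0.20, DENSE = 0.20,
            GRASSLAND = 0.15, SHRUBLAND = 0.15),
      B = c(BARE_PATH = 0.30, BURNED = 0.20, DENSE = 0.20,
            GRASSLAND = 0.15, SHRUBLAND = 0.15))
  }
  n_locations <- as.integer(n_locations)
  stopifnot(n_locations >= 1, n_points_per_location >= 1)
  if (length(habitat_types) != n_locations) {
    stop("habitat_types must have one element per location")
  }
  for (h in habitat_types) {
    if (abs(sum(h) - 1) > 1e-8) {
      stop("habitat allocation proportions must sum to 1")
    }
  }
  if (quadrat_grid != 4L) {
    stop("quadrat_grid must be 4: each point carries a 4x4 grid of ",
         "25x25 cm cells")
  }
  if (any(min_larvae_threshold < 0)) {
    stop("min_larvae_threshold must be >= 0")
  }
  recycle <- function(x) rep_len(x, n_locations)
  out <- list(
    n_locations = n_locations,
    n_points_per_location = as.integer(n_points_per_location),
    habitat_types = habitat_types,
    min_point_spacing = min_point_spacing,
    area_side = recycle(area_side),
    quadrat_grid = 4L,
    min_larvae_threshold = as.integer(recycle(min_larvae_threshold)),
    fine_scale_points_cap = as.integer(recycle(fine_scale_points_cap)),
    location_labels = names(habitat_types))
  class(out) <- "survey_design"
  out
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", x$n_locations, "location(s) x",
      x$n_points_per_location, "points,",
      x$quadrat_grid^2, "cells/point\n")
  cat("  min spacing:", x$min_point_spacing, "m; fine-scale thresholds:",
      paste(x$min_larvae_threshold, collapse = "/"), "larvae, caps:",
      paste(x$fine_scale_points_cap, collapse = "/"), "points\n")
  invisible(x)
}

#' Ground truth for the synthetic survey generator
#'
#' Bundles the generating model of the synthetic survey: the covariate
#' model (habitat-type means on the latent scale and the cross-scale
#' correlation linking the 25 cm / 50 cm / 1 m versions of each cover
#' variable), one linear-predictor specification per response (adult
#' occupancy and abundance, larval point totals, the congeneric species),
#' cell-level allocation weights, and the negative-binomial clumping
#' parameters.
#'
#' Coefficient vectors are named by catalog variable (abiotic terms) or by
#' biotic term (`ADULT_PA`, `CONGEN_ADULT_AB`, ...). Linear predictors are
#' `intercept + sum(coef * column)` on the logit (presence-absence) or log
#' (count) scale.
#'
#' @param cross_scale_rho correlation between any two scale versions of the
#'   same cover variable (on the latent scale), in `[0, 1]`.
#' @param habitat_means named list: per latent habitat gradient
#'   (`bare`, `herb`, `shrub`), a named numeric vector of logit-scale means
#'   per habitat type. Defaults describe heathland bare-ground mosaics.
#' @param adult_pa,adult_ab,larva_ab,congen_adult_ab,congen_larva_ab lists
#'   with `intercept` and named `coef` vectors (see Details).
#' @param cell_coef named coefficients of the cell-level log-weight model
#'   used to spread a point's larval total over its 16 cells.
#' @param k named numeric clumping parameters (`adult_ab`, `larva_ab`,
#'   `congen_adult_ab`, `congen_larva_ab`); all must be positive.
#' @param latent_sd standard deviation of the latent logit-scale covariate
#'   values.
#' @return An object of class `synthetic_truth`.
#' @examples
#' tr <- synthetic_truth()
#' tr$k
#' @export
synthetic_truth <- function(cross_scale_rho = 0.8,
                            habitat_means = NULL,
                            adult_pa = NULL,
                            adult_ab = NULL,
                            larva_ab = NULL,
                            congen_adult_ab = NULL,
                            congen_larva_ab = NULL,
                            cell_coef = c(BARESOIL_25 = 0.04),
                            k = c(adult_ab = 1.5, larva_ab = 1.2,
                                  congen_adult_ab = 1.0,
                                  congen_larva_ab = 1.0),
                            latent_sd = 1.0) {
  stopifnot(cross_scale_rho >= 0, cross_scale_rho <= 1, all(k > 0))
  if (is.null(habitat_means)) {
    # logit-scale means of the three dominant cover gradients per habitat
    habitat_means <- list(
      bare = c(BARE_CUSHION = -0.2, BARE_SPOT = -1.1, BARE_PATH = -0.7,
               BURNED = -1.2, DENSE = -3.0, GRASSLAND = -2.2,
               SHRUBLAND = -2.5),
      herb = c(BARE_CUSHION = -1.5, BARE_SPOT = -1.2, BARE_PATH = -1.5,
               BURNED = -1.0, DENSE = -2.0, GRASSLAND = 0.5,
               SHRUBLAND = -1.5),
      shrub = c(BARE_CUSHION = 0.0, BARE_SPOT = 0.5, BARE_PATH = 0.0,
                BURNED = -0.5, DENSE = 1.5, GRASSLAND = -2.5,
                SHRUBLAND = 1.0))
  }
  if (is.null(adult_pa)) {
    adult_pa <- list(intercept = -1.7,
                     coef = c(BARESOIL_1 = 0.06, HERB_1 = -0.03,
                              CONGEN_ADULT_PA = 0.4))
  }
  if (is.null(adult_ab)) {
    adult_ab <- list(intercept = -1.9,
                     coef = c(BARESOIL_1 = 0.05, HERB_1 = -0.02,
                              CONGEN_ADULT_PA = 0.3))
  }
  if (is.null(larva_ab)) {
    larva_ab <- list(intercept = -0.5,
                     coef = c(BARESOIL_1 = 0.06, HERB_1 = -0.03,
                              VACCINIUM_1 = -0.015, ADULT_PA = 0.5))
  }
  if (is.null(congen_adult_ab)) {
    congen_adult_ab <- list(intercept = -2.0, coef = c(BARESOIL_1 = 0.03))
  }
  if (is.null(congen_larva_ab)) {
    congen_larva_ab <- list(intercept = -2.2, coef = c(BARESOIL_1 = 0.035))
  }
  out <- list(cross_scale_rho = cross_scale_rho,
              habitat_means = habitat_means,
              stage_models = list(adult_pa = adult_pa,
                                  adult_ab = adult_ab,
                                  larva_ab = larva_ab,
                                  congen_adult_ab = congen_adult_ab,
                                  congen_larva_ab = congen_larva_ab),
              cell_coef = cell_coef,
              k = k,
              latent_sd = latent_sd)
  class(out) <- "synthetic_truth"
  out
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic survey truth: cross-scale rho =", x$cross_scale_rho, "\n")
  for (nm in names(x$stage_models)) {
    m <- x$stage_models[[nm]]
    cat(sprintf("  %-16s intercept %.2f; terms: %s\n", nm, m$intercept,
                paste(names(m$coef), collapse = ", ")))
  }
  invisible(x)
}
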