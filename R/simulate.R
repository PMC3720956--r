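# Synthetic survey generator: stratified sampling points with minimum
# spacing, the Table-2-style abiotic covariate catalog at nested scales,
# GLM-structured stage responses, and per-point 4x4 larval cell maps.

#' Generate abiotic covariates for a synthetic survey
#'
#' Places the sampling points of each location uniformly at random inside a
#' square extent, rejection-sampled to respect the minimum point spacing,
#' assigns habitat types by proportional stratification, and draws every
#' variable of the abiotic catalog. Percentage-cover variables are drawn
#' from logit-normal distributions with habitat-specific means; the three
#' scale versions (25 cm / 50 cm / 1 m) of each cover variable share a
#' latent per-point value so that any two scales correlate at
#' `truth$cross_scale_rho` on the latent scale. The 16 cells of the 4x4
#' quadrat grid receive their own 25 cm cover values from the same latent;
#' the point-level `_25` column is the value of a fixed central reference
#' cell.
#'
#' @param design a [survey_design()].
#' @param truth a [synthetic_truth()].
#' @param seed optional integer seed; when supplied the RNG is seeded
#'   before generation so repeated calls are bit-identical.
#' @return A data.frame with one row per sampling point (columns
#'   `location`, `point_id`, `habitat_type`, `x`, `y` and every abiotic
#'   catalog variable), carrying the cell-level 25 cm cover values as the
#'   `cells` attribute.
#' @export
generate_covariates <- function(design, truth, seed = NULL) {
  stopifnot(inherits(design, "survey_design"),
            inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  locs <- design$location_labels
  pts <- vector("list", design$n_locations)
  cells <- vector("list", design$n_locations)
  for (i in seq_len(design$n_locations)) {
    xy <- place_points(design$n_points_per_location,
                       design$area_side[i], design$min_point_spacing)
    hab <- stratify_habitats(design$habitat_types[[i]],
                             design$n_points_per_location)
    base <- data.frame(
      location = locs[i],
      point_id = seq_len(design$n_points_per_location),
      habitat_type = hab,
      x = xy[, 1], y = xy[, 2],
      stringsAsFactors = FALSE)
    drawn <- draw_abiotic(base, truth, design$quadrat_grid)
    pts[[i]] <- drawn$points
    cells[[i]] <- drawn$cells
  }
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  cell_tbl <- do.call(rbind, cells)
  rownames(cell_tbl) <- NULL
  attr(out, "cells") <- cell_tbl
  out
}

# Rejection-sample n points in [0, side]^2 with pairwise spacing >= min_d.
place_points <- function(n, side, min_d, max_tries = 200L) {
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cx <- stats::runif(1, 0, side); cy <- stats::runif(1, 0, side)
      if (i == 1L ||
          min((xs[seq_len(i - 1)] - cx)^2 +
              (ys[seq_len(i - 1)] - cy)^2) >= min_d^2) {
        xs[i] <- cx; ys[i] <- cy; ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not place ", n, " points with minimum spacing ", min_d,
           " m inside a ", side, " m square (constraint infeasible)")
    }
  }
  cbind(x = xs, y = ys)
}

# Proportional stratification: largest-remainder allocation of n points to
# habitat types, order randomized across points.
stratify_habitats <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(props), counts))
}

# Latent logit-scale mean for each cover variable: a loading on one of the
# three habitat gradients plus a variable-specific offset.
cover_mu_spec <- function() {
  list(
    BARESOIL  = c(g = "bare",  load = 1.0, off = 0.0),
    STONE     = c(g = "bare",  load = 0.5, off = -2.0),
    LICHEN    = c(g = "bare",  load = 0.2, off = -2.5),
    HERB      = c(g = "herb",  load = 1.0, off = 0.0),
    GRAMINOID = c(g = "herb",  load = 1.0, off = -0.5),
    CALLUNA   = c(g = "shrub", load = 1.0, off = 0.0),
    SHRUB     = c(g = "shrub", load = 1.0, off = 0.3),
    VACCINIUM = c(g = "shrub", load = 0.7, off = -1.0),
    LITTER    = c(g = "shrub", load = 0.3, off = -1.5),
    MOSS      = c(g = "bare",  load = -0.3, off = -2.0),
    DUNG      = c(g = "bare",  load = 0.0, off = -3.5),
    ROOT      = c(g = "bare",  load = 0.0, off = -3.0),
    SEDUM     = c(g = "bare",  load = 0.3, off = -4.0),
    WOOD      = c(g = "shrub", load = 0.2, off = -4.0))
}

draw_abiotic <- function(base, truth, grid) {
  n <- nrow(base)
  hm <- truth$habitat_means
  grad <- function(g) unname(hm[[g]][base$habitat_type])
  sd0 <- truth$latent_sd
  a <- sqrt(truth$cross_scale_rho)
  b <- sqrt(1 - truth$cross_scale_rho)
  n_cells <- grid^2
  ref_cell <- 6L  # row 2, col 2 of the 4x4 grid: a central cell

  pts <- base
  cell_tbl <- data.frame(
    location = rep(base$location, each = n_cells),
    point_id = rep(base$point_id, each = n_cells),
    cell = rep(seq_len(n_cells), n),
    row = rep(rep(seq_len(grid), each = grid), n),
    col = rep(rep(seq_len(grid), times = grid), n),
    stringsAsFactors = FALSE)

  # COVER: shared latent + per-scale / per-cell noise, logit-normal in %
  for (v in names(cover_mu_spec())) {
    sp <- cover_mu_spec()[[v]]
    mu <- as.numeric(sp["load"]) * grad(sp["g"]) + as.numeric(sp["off"])
    z <- stats::rnorm(n)
    val_scale <- function(eps) 100 * stats::plogis(mu + sd0 * (a * z + b * eps))
    cell_eps <- matrix(stats::rnorm(n * n_cells), nrow = n)
    cell_val <- 100 * stats::plogis(mu + sd0 * (a * z + b * cell_eps))
    pts[[paste0(v, "_1")]] <- val_scale(stats::rnorm(n))
    pts[[paste0(v, "_50")]] <- val_scale(stats::rnorm(n))
    pts[[paste0(v, "_25")]] <- cell_val[, ref_cell]
    cell_tbl[[paste0(v, "_25")]] <- as.vector(t(cell_val))
  }

  # RESISTANCE (1 m): vegetation density tracks the shrub gradient
  dens <- grad("shrub")
  for (d in c("N", "E", "S", "W")) {
    pts[[paste0("COVER_", d)]] <-
      100 * stats::plogis(dens + stats::rnorm(n, sd = sd0))
    pts[[paste0("SQUARE_", d)]] <-
      stats::rbinom(n, 36, stats::plogis(dens + stats::rnorm(n, sd = 0.5)))
  }
  pts$HEIGHT <- exp(stats::rnorm(n, log(30) + 0.15 * dens, 0.3))

  # SOIL (1 m): particle-size fractions sum to 100 via Dirichlet draws
  shapes <- c(2, 3, 5, 6, 4, 2)
  g <- matrix(stats::rgamma(n * 6, shape = rep(shapes, each = n)), nrow = n)
  frac <- 100 * g / rowSums(g)
  soil_names <- c("SOIL_0.063", "SOIL_0.125", "SOIL_0.25", "SOIL_0.50",
                  "SOIL_1", "SOIL_2")
  for (j in seq_along(soil_names)) pts[[soil_names[j]]] <- frac[, j]
  pts$LITTER_DEPTH <- exp(stats::rnorm(n, log(2) + 0.2 * dens, 0.4))
  pts$SOIL_HUMID <- 100 * stats::plogis(stats::rnorm(n, -1, 0.6))
  pts$SOIL_OM <- 100 * stats::plogis(stats::rnorm(n, -1.5, 0.5))
  pts$SOIL_PH <- stats::rnorm(n, 4.5, 0.3)

  # STRUCTURE (3 m / 6 m radii): open patches track the bare gradient,
  # tall shrubs the shrub gradient; 3 m counts are thinned 6 m counts
  bare_z <- grad("bare") + stats::rnorm(n, sd = 0.5)
  pts$OPEN_6 <- stats::rpois(n, exp(1.2 + 0.5 * (bare_z + 2) / 2))
  pts$OPEN_3 <- stats::rbinom(n, pts$OPEN_6, 0.35)
  shrub_z <- dens + stats::rnorm(n, sd = 0.5)
  pts$SHRUB_6 <- stats::rpois(n, exp(0.8 + 0.4 * shrub_z))
  pts$SHRUB_3 <- stats::rbinom(n, pts$SHRUB_6, 0.35)
  ord <- function(zz) pmin(pmax(round(3 + 1.2 * zz + stats::rnorm(n, sd = 0.7)),
                                1), 6)
  pts$STRUCTURE_6 <- ord(bare_z)
  pts$STRUCTURE_3 <- ord(bare_z + stats::rnorm(n, sd = 0.3))
  pts$DIST_OPEN <- exp(stats::rnorm(n, log(150) - 0.5 * bare_z, 0.5))
  pts$DIST_SHRUB <- exp(stats::rnorm(n, log(120) - 0.4 * shrub_z, 0.5))

  list(points = pts, cells = cell_tbl)
}

# Evaluate intercept + sum(coef * column) on a table; linear predictors are
# clipped to +/- 30 before inverse-link to avoid overflow, with a message
# when clipping occurs.
eval_linpred <- function(tbl, model, label = "model") {
  eta <- rep(model$intercept, nrow(tbl))
  for (v in names(model$coef)) {
    if (!v %in% names(tbl)) {
      stop("linear predictor of ", label, " references missing column ", v)
    }
    eta <- eta + model$coef[[v]] * tbl[[v]]
  }
  n_clip <- sum(abs(eta) > 30)
  if (n_clip > 0) {
    message("clipped ", n_clip, " linear-predictor values of ", label,
            " to +/-30")
    eta <- pmin(pmax(eta, -30), 30)
  }
  eta
}

#' Generate stage responses for a synthetic survey
#'
#' Draws the responses of both species from the truth's GLM structure:
#' congeneric adult and larval abundances first (negative binomial,
#' log link), then target-species adult presence-absence (Bernoulli, logit
#' link) and abundance (negative binomial), then the larval point totals
#' (negative binomial, with adult presence as a biotic term). Each point's
#' larval total is spread over its 16 25x25 cm cells by a multinomial draw
#' with cell weights `exp(cell_coef \%*\% cell covariates)`, so cell sums
#' reproduce the 1x1 m total exactly and the central 2x2 block gives the
#' 50x50 cm abundance.
#'
#' @param covariates point table from [generate_covariates()] (must carry
#'   its `cells` attribute).
#' @param truth the [synthetic_truth()] used for the covariates.
#' @param seed optional integer seed.
#' @return An object of class `stageniche_survey`: a list with `points`
#'   (covariates plus response columns), `cells` (cell covariates plus
#'   `larvae` counts) and the `truth`.
#' @export
generate_responses <- function(covariates, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- attr(covariates, "cells")
  if (is.null(cells)) stop("covariates must carry the 'cells' attribute")
  pts <- as.data.frame(covariates)
  n <- nrow(pts)
  sm <- truth$stage_models

  rnb <- function(eta, k) {
    stats::rnbinom(length(eta), size = k, mu = exp(eta))
  }

  pts$CONGEN_ADULT_AB <- rnb(eval_linpred(pts, sm$congen_adult_ab,
                                          "congen_adult_ab"),
                             truth$k[["congen_adult_ab"]])
  pts$CONGEN_ADULT_PA <- as.integer(pts$CONGEN_ADULT_AB > 0)
  pts$CONGEN_LARVA_AB <- rnb(eval_linpred(pts, sm$congen_larva_ab,
                                          "congen_larva_ab"),
                             truth$k[["congen_larva_ab"]])
  pts$CONGEN_LARVA_PA <- as.integer(pts$CONGEN_LARVA_AB > 0)

  pts$ADULT_PA <- stats::rbinom(n, 1,
                                stats::plogis(eval_linpred(pts, sm$adult_pa,
                                                           "adult_pa")))
  pts$ADULT_AB <- rnb(eval_linpred(pts, sm$adult_ab, "adult_ab"),
                      truth$k[["adult_ab"]])

  pts$LARVA_AB <- rnb(eval_linpred(pts, sm$larva_ab, "larva_ab"),
                      truth$k[["larva_ab"]])
  pts$LARVA_PA <- as.integer(pts$LARVA_AB > 0)

  # multinomial spread of each point total over its 16 cells
  cell_eta <- rep(0, nrow(cells))
  for (v in names(truth$cell_coef)) {
    cell_eta <- cell_eta + truth$cell_coef[[v]] * cells[[v]]
  }
  cells$larvae <- 0L
  key <- paste(cells$location, cells$point_id)
  pkey <- paste(pts$location, pts$point_id)
  idx <- split(seq_len(nrow(cells)), key)
  for (i in seq_len(n)) {
    rows <- idx[[pkey[i]]]
    total <- pts$LARVA_AB[i]
    if (total > 0) {
      w <- exp(cell_eta[rows] - max(cell_eta[rows]))
      cells$larvae[rows] <- as.integer(
        stats::rmultinom(1, total, prob = w / sum(w)))
    }
  }

  out <- list(points = pts, cells = cells, truth = truth)
  class(out) <- "stageniche_survey"
  out
}

#' @export
print.stageniche_survey <- function(x, ...) {
  cat("Synthetic survey:", nrow(x$points), "points (",
      paste(unique(x$points$location), collapse = ", "), "),",
      nrow(x$cells), "cells\n")
  cat("  adult prevalence:", round(mean(x$points$ADULT_PA), 3),
      "; larvae/point:", round(mean(x$points$LARVA_AB), 2), "\n")
  invisible(x)
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper: seeds the RNG once, generates covariates and
#' responses.
#'
#' @inheritParams generate_covariates
#' @return A `stageniche_survey` (see [generate_responses()]), with the
#'   design attached as `$design`.
#' @examples
#' sv <- simulate_survey(seed = 1)
#' head(sv$points[, c("location", "point_id", "LARVA_AB")])
#' @export
simulate_survey <- function(design = survey_design(),
                            truth = synthetic_truth(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- generate_covariates(design, truth)
  sv <- generate_responses(cov, truth)
  sv$design <- design
  sv
}

#' Neighbour larval counts on the 4x4 cell grid
#'
#' Counts larvae in the cells bordering a focal quadrat of one sampling
#' point. For the 50x50 cm focal (the central 2x2 block) the neighbourhood
#' is the ring of 12 cells surrounding the block. For a 25x25 cm focal (a
#' single cell) it is the cell's 8-neighbourhood clipped to the grid: 3
#' cells at a corner, 5 on an edge, 8 in the interior. Neighbourhoods never
#' extend beyond the point's own grid.
#'
#' @param map 4x4 integer matrix of larval counts (`map[row, col]`).
#' @param focal either the string `"central"` (the 50x50 cm block) or an
#'   integer vector `c(row, col)` naming one cell.
#' @return Integer: summed count over the neighbour cells.
#' @examples
#' m <- matrix(1L, 4, 4)
#' neighbour_counts(m, "central")  # 12-cell ring
#' neighbour_counts(m, c(1, 1))   # corner: 3 neighbours
#' @export
neighbour_counts <- function(map, focal) {
  stopifnot(is.matrix(map), all(dim(map) == c(4, 4)), all(map >= 0))
  if (identical(focal, "central")) {
    ring <- !(row(map) %in% 2:3 & col(map) %in% 2:3)
    return(sum(map[ring]))
  }
  r <- focal[1]; c <- focal[2]
  if (r < 1 || r > 4 || c < 1 || c > 4) {
    stop("focal cell (", r, ",", c, ") outside the 4x4 grid")
  }
  rows <- max(1, r - 1):min(4, r + 1)
  cols <- max(1, c - 1):min(4, c + 1)
  sum(map[rows, cols]) - map[r, c]
}

# All 16 per-cell 8-neighbourhood sums of a 4x4 matrix, as a matrix.
cell_neighbour_matrix <- function(map) {
  out <- matrix(0L, 4, 4)
  for (r in 1:4) for (c in 1:4) out[r, c] <- neighbour_counts(map, c(r, c))
  out
}

# Scale scopes of the abiotic predictor sets per data-set type (which
# scale versions of the catalog enter each analysis).
abiotic_scope <- function(type, catalog = variable_catalog()) {
  cover_scales <- switch(type,
    adult = c("50cm", "1m"),
    larva_1m = "1m",
    larva_50cm = c("50cm", "1m"),
    larva_25cm = c("25cm", "1m"),
    stop("unknown data-set type: ", type))
  keep <- (catalog$category == "COVER" & catalog$scale %in% cover_scales) |
    catalog$category %in% c("RESISTANCE", "SOIL", "STRUCTURE")
  catalog$name[keep]
}

new_observation_table <- function(df, dataset_id, location, stage, scale,
                                  abiotic, biotic) {
  rownames(df) <- NULL
  structure(df, dataset_id = dataset_id, location = location,
            stage = stage, sampling_scale = scale,
            abiotic = abiotic, biotic = biotic,
            class = c("observation_table", "data.frame"))
}

#' Predictor column names of an observation table
#'
#' @param table an observation table produced by [assemble_datasets()] or
#'   [read_observation_table()].
#' @return Character vector of abiotic (resp. biotic) predictor columns.
#' @export
abiotic_vars <- function(table) attr(table, "abiotic")

#' @rdname abiotic_vars
#' @export
biotic_vars <- function(table) attr(table, "biotic")

#' Assemble the eight analysis data sets
#'
#' Builds one observation table per location and sampling unit: adult
#' (pitfall trap), larva at 1x1 m, larva at 50x50 cm, and larva at
#' 25x25 cm. Coarse-scale tables have one row per sampling point. The
#' fine-scale tables keep only points whose mapped larval total reaches the
#' location's minimum-larvae threshold, rank them by descending total
#' (ties broken by ascending point id), cap them at the location's
#' fine-scale cap, and expand each retained point to its 16 cell rows.
#' Each table carries its abiotic scope (scale versions per the study
#' design) and biotic predictors (stage co-occurrence, congeneric species,
#' neighbour larval counts) as attributes.
#'
#' @param survey a `stageniche_survey` from [simulate_survey()].
#' @param design the [survey_design()]; defaults to the one stored in the
#'   survey.
#' @return Named list of observation tables (`ds1` ... `ds8` with the
#'   default two-location design: odd ids = first location). Each has
#'   attributes `dataset_id`, `location`, `stage`, `sampling_scale`,
#'   `abiotic`, `biotic` and columns `PA` and `AB`.
#' @examples
#' sv <- simulate_survey(seed = 1)
#' ds <- assemble_datasets(sv)
#' sapply(ds, nrow)
#' @export
assemble_datasets <- function(survey, design = survey$design) {
  stopifnot(inherits(survey, "stageniche_survey"))
  if (is.null(design)) stop("no survey design available")
  pts <- survey$points
  cells <- survey$cells
  locs <- design$location_labels
  types <- c("adult", "larva_1m", "larva_50cm", "larva_25cm")
  out <- list()
  ds_id <- 0L
  for (type in types) {
    for (li in seq_along(locs)) {
      ds_id <- ds_id + 1L
      loc <- locs[li]
      p <- pts[pts$location == loc, , drop = FALSE]
      tab <- switch(type,
        adult = build_adult_table(p),
        larva_1m = build_larva_1m_table(p),
        larva_50cm = build_larva_50cm_table(p, cells),
        larva_25cm = build_larva_25cm_table(
          p, cells, design$min_larvae_threshold[li],
          design$fine_scale_points_cap[li]))
      out[[paste0("ds", ds_id)]] <- new_observation_table(
        tab$df, ds_id, loc,
        stage = if (type == "adult") "adult" else "larva",
        scale = switch(type, adult = "trap", larva_1m = "1m",
                       larva_50cm = "50cm", larva_25cm = "25cm"),
        abiotic = abiotic_scope(type), biotic = tab$biotic)
    }
  }
  # interleave so data sets follow the life-stage/scale-by-location order:
  # 1-2 adult, 3-4 larva 1m, 5-6 larva 50cm, 7-8 larva 25cm
  out
}

meta_cols <- function(p) {
  data.frame(unit_id = paste(p$location, p$point_id, sep = "_"),
             location = p$location, point_id = p$point_id,
             habitat_type = p$habitat_type, x = p$x, y = p$y,
             stringsAsFactors = FALSE)
}

build_adult_table <- function(p) {
  df <- cbind(meta_cols(p), PA = p$ADULT_PA, AB = p$ADULT_AB,
              p[, abiotic_scope("adult"), drop = FALSE],
              LARVA_PA = p$LARVA_PA, LARVA_AB = p$LARVA_AB,
              CONGEN_ADULT_PA = p$CONGEN_ADULT_PA,
              CONGEN_ADULT_AB = p$CONGEN_ADULT_AB)
  list(df = df, biotic = c("LARVA_PA", "LARVA_AB",
                           "CONGEN_ADULT_PA", "CONGEN_ADULT_AB"))
}

build_larva_1m_table <- function(p) {
  df <- cbind(meta_cols(p), PA = p$LARVA_PA, AB = p$LARVA_AB,
              p[, abiotic_scope("larva_1m"), drop = FALSE],
              ADULT_PA = p$ADULT_PA, ADULT_AB = p$ADULT_AB,
              CONGEN_LARVA_PA = p$CONGEN_LARVA_PA,
              CONGEN_LARVA_AB = p$CONGEN_LARVA_AB)
  list(df = df, biotic = c("ADULT_PA", "ADULT_AB",
                           "CONGEN_LARVA_PA", "CONGEN_LARVA_AB"))
}

# 4x4 count matrix of one point, rows/cols in grid order
point_cell_matrix <- function(cells, loc, pid, col = "larvae") {
  cc <- cells[cells$location == loc & cells$point_id == pid, , drop = FALSE]
  m <- matrix(0L, 4, 4)
  m[cbind(cc$row, cc$col)] <- cc[[col]]
  m
}

build_larva_50cm_table <- function(p, cells) {
  n <- nrow(p)
  ab <- integer(n); neigh <- integer(n)
  for (i in seq_len(n)) {
    m <- point_cell_matrix(cells, p$location[i], p$point_id[i])
    ab[i] <- sum(m[2:3, 2:3])
    neigh[i] <- neighbour_counts(m, "central")
  }
  df <- cbind(meta_cols(p), PA = as.integer(ab > 0), AB = ab,
              p[, abiotic_scope("larva_50cm"), drop = FALSE],
              ADULT_PA = p$ADULT_PA, ADULT_AB = p$ADULT_AB,
              NEIGH_LARVA_AB = neigh)
  list(df = df, biotic = c("ADULT_PA", "ADULT_AB", "NEIGH_LARVA_AB"))
}

build_larva_25cm_table <- function(p, cells, threshold, cap) {
  totals <- vapply(seq_len(nrow(p)), function(i) {
    sum(point_cell_matrix(cells, p$location[i], p$point_id[i]))
  }, numeric(1))
  pass <- which(totals >= threshold)
  if (length(pass) < cap) {
    message("only ", length(pass), " points reach the larval threshold (",
            threshold, "); cap of ", cap, " not filled")
  }
  ord <- pass[order(-totals[pass], p$point_id[pass])]
  keep <- ord[seq_len(min(cap, length(ord)))]
  if (length(keep) == 0) {
    empty <- cbind(meta_cols(p[0, , drop = FALSE]),
                   PA = integer(0), AB = integer(0),
                   p[0, abiotic_scope("larva_25cm"), drop = FALSE],
                   ADULT_AB = integer(0), NEIGH_LARVA_AB = integer(0))
    return(list(df = empty, biotic = c("ADULT_AB", "NEIGH_LARVA_AB")))
  }

  rows <- list()
  for (i in keep) {
    loc <- p$location[i]; pid <- p$point_id[i]
    cc <- cells[cells$location == loc & cells$point_id == pid, , drop = FALSE]
    cc <- cc[order(cc$cell), , drop = FALSE]
    m <- point_cell_matrix(cells, loc, pid)
    nb <- cell_neighbour_matrix(m)
    meta <- meta_cols(p[rep(i, nrow(cc)), , drop = FALSE])
    meta$unit_id <- paste(meta$unit_id, cc$cell, sep = "_")
    meta$x <- meta$x + (cc$col - 2.5) * 0.25
    meta$y <- meta$y + (cc$row - 2.5) * 0.25
    point_level <- p[rep(i, nrow(cc)),
                     setdiff(abiotic_scope("larva_25cm"),
                             paste0(names(cover_mu_spec()), "_25")),
                     drop = FALSE]
    cell_level <- cc[, paste0(names(cover_mu_spec()), "_25"), drop = FALSE]
    df_i <- cbind(meta,
                  PA = as.integer(cc$larvae > 0), AB = cc$larvae,
                  cell_level, point_level,
                  ADULT_AB = p$ADULT_AB[i],
                  NEIGH_LARVA_AB = nb[cbind(cc$row, cc$col)])
    rows[[length(rows) + 1L]] <- df_i
  }
  df <- do.call(rbind, rows)
  # column order: meta, responses, abiotic scope, biotic
  df <- df[, c(names(meta_cols(p[1, , drop = FALSE])), "PA", "AB",
               abiotic_scope("larva_25cm"), "ADULT_AB", "NEIGH_LARVA_AB")]
  list(df = df, biotic = c("ADULT_AB", "NEIGH_LARVA_AB"))
}
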