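# Spatial autocorrelation of model residuals: Moran's I, permutation
# significance, Holm correction across the models of a run.

#' Spatial weight matrix for irregular survey points
#'
#' Default: row-standardized inverse distance. Alternative: symmetric
#' k-nearest-neighbour adjacency (also row-standardized). Coincident
#' points are kept apart by a small distance floor.
#'
#' @param coords two-column matrix or data.frame of x/y coordinates.
#' @param type `"inverse_distance"` or `"knn"`.
#' @param k neighbours for `type = "knn"`.
#' @param dist_floor minimum distance substituted for coincident points.
#' @return n x n weight matrix with zero diagonal, rows summing to 1.
#' @export
moran_weights <- function(coords, type = c("inverse_distance", "knn"),
                          k = 8, dist_floor = 1e-6) {
  type <- match.arg(type)
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] < dist_floor)) {
    message("coincident points: distance floor ", dist_floor, " applied")
    d[d < dist_floor] <- dist_floor
  }
  n <- nrow(d)
  if (type == "inverse_distance") {
    w <- 1 / d
    diag(w) <- 0
  } else {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      w[i, nb] <- 1
    }
    w <- pmax(w, t(w))  # symmetrize
  }
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Moran's I
#'
#' `I = n / S0 * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` with `z` the
#' centered values and `S0` the sum of all weights.
#'
#' @param values numeric vector (e.g. model residuals); must be
#'   non-constant.
#' @param coords point coordinates (ignored when `weights` is a matrix).
#' @param weights either a weight matrix with zero diagonal or a type
#'   string passed to [moran_weights()].
#' @return Moran's I value.
#' @examples
#' xy <- cbind(runif(50), runif(50))
#' morans_i(xy[, 1] + rnorm(50, 0, 0.1), xy)
#' @export
morans_i <- function(values, coords = NULL,
                     weights = "inverse_distance") {
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("Moran's I undefined: constant values")
  w <- resolve_weights(values, coords, weights)
  z <- values - mean(values)
  n <- length(z)
  (n / sum(w)) * as.numeric(z %*% w %*% z) / sum(z^2)
}

resolve_weights <- function(values, coords, weights) {
  if (is.matrix(weights)) {
    if (any(diag(weights) != 0)) stop("weight matrix must have zero diagonal")
    if (nrow(weights) != length(values)) {
      stop("weight matrix dimension does not match values")
    }
    weights
  } else {
    if (is.null(coords)) stop("coords required to build spatial weights")
    moran_weights(coords, type = weights)
  }
}

#' Permutation test for Moran's I
#'
#' Permutes the values over the locations and recomputes I;
#' `p = (1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (n_perm + 1)`, with
#' `E[I] = -1/(n-1)` (two-sided, the default) or the one-sided "clumped"
#' alternative `I_perm >= I_obs`.
#'
#' @inheritParams morans_i
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alternative `"two.sided"` or `"greater"` (positive
#'   autocorrelation only).
#' @return List of class `moran_test`: `observed` I, `p_value`,
#'   `n_perm`, `alternative`.
#' @export
moran_permutation_test <- function(values, coords = NULL,
                                   weights = "inverse_distance",
                                   n_perm = 1000, seed = 1,
                                   alternative = c("two.sided",
                                                   "greater")) {
  alternative <- match.arg(alternative)
  w <- resolve_weights(values, coords, weights)
  n <- length(values)
  i_obs <- morans_i(values, weights = w)
  e_i <- -1 / (n - 1)
  set.seed(seed)
  z <- values - mean(values)
  s2 <- sum(z^2)
  c0 <- n / sum(w)
  i_perm <- vapply(seq_len(n_perm), function(b) {
    zp <- z[sample.int(n)]
    c0 * as.numeric(zp %*% w %*% zp) / s2
  }, numeric(1))
  extreme <- if (alternative == "two.sided") {
    abs(i_perm - e_i) >= abs(i_obs - e_i)
  } else {
    i_perm >= i_obs
  }
  p <- (1 + sum(extreme)) / (n_perm + 1)
  structure(list(observed = i_obs, expected = e_i, p_value = p,
                 n_perm = n_perm, alternative = alternative),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g (%s, %d perms)\n",
              x$observed, x$expected, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' Holm step-down adjustment of p-values
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Moran's I report across the models of a run
#'
#' Tests the residuals of each fitted model for spatial autocorrelation
#' and applies the Holm correction across all models (the family is the
#' whole run).
#'
#' @param models named list of `fitted_niche_model`s.
#' @param tables named list (parallel to `models`) of the observation
#'   tables the models were fitted on, providing `x`/`y` coordinates.
#' @param residual_type residual type tested (`"deviance"`, `"pearson"`
#'   or `"response"`).
#' @param n_perm permutations per test.
#' @param seed base seed; test `i` uses `seed + i`.
#' @param alpha familywise significance level.
#' @param weights weight type passed to [moran_weights()].
#' @return data.frame with one row per model: `model`, `moran_i`, `p`,
#'   `p_holm`, `significant`.
#' @export
moran_report <- function(models, tables, residual_type = "deviance",
                         n_perm = 1000, seed = 1, alpha = 0.05,
                         weights = "inverse_distance") {
  stopifnot(length(models) == length(tables))
  rows <- lapply(seq_along(models), function(i) {
    res <- as.numeric(stats::residuals(models[[i]]$fit,
                                       type = residual_type))
    coords <- cbind(tables[[i]]$x, tables[[i]]$y)
    tst <- moran_permutation_test(res, coords, weights = weights,
                                  n_perm = n_perm, seed = seed + i)
    data.frame(model = names(models)[i], moran_i = tst$observed,
               p = tst$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out$significant <- out$p_holm < alpha
  attr(out, "residual_type") <- residual_type
  attr(out, "weights") <- if (is.character(weights)) weights else "custom"
  out
}
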