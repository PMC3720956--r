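# Predictive-accuracy evaluation: AUC (presence-absence) and Spearman rho
# (abundance), repeated 2-fold internal cross-validation, cross-location
# external evaluation, and the qualitative accuracy bands.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `AUC = P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 observed labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman rank correlation between predictions and observations
#'
#' Pearson correlation of midranks.
#'
#' @param pred predicted values.
#' @param obs observed values.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) < 3) stop("need at least 3 observations")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("Spearman rho undefined for constant input")
  }
  stats::cor(pred, obs, method = "spearman")
}

#' Qualitative accuracy band of a metric value
#'
#' AUC bands: excellent > 0.90, good 0.80-0.90, fair 0.70-0.80, poor
#' 0.60-0.70, fail below 0.60. Spearman bands: excellent > 0.80, good
#' 0.60-0.80, fair 0.40-0.60, poor 0.20-0.40, fail below 0.20. Intervals
#' are closed on the left (0.80 is "good" for AUC, 0.20 is "poor" for
#' rho).
#'
#' @param metric `"AUC"` or `"rho"`.
#' @param value metric value.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`, `"fail"`.
#' @export
classify_band <- function(metric = c("AUC", "rho"), value) {
  metric <- match.arg(metric)
  cuts <- if (metric == "AUC") c(0.60, 0.70, 0.80, 0.90) else
    c(0.20, 0.40, 0.60, 0.80)
  labels <- c("fail", "poor", "fair", "good", "excellent")
  labels[findInterval(value, cuts, left.open = FALSE) + 1L]
}

new_evaluation_result <- function(metric, value, mode, per_iteration = NULL,
                                  calibration_id = NA, evaluation_id = NA) {
  structure(list(metric = metric, value = value,
                 band = classify_band(metric, value), mode = mode,
                 per_iteration = per_iteration,
                 calibration_id = calibration_id,
                 evaluation_id = evaluation_id),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("%s evaluation: %s = %.3f (%s)\n", x$mode, x$metric,
              x$value, x$band))
  invisible(x)
}

eval_metric <- function(pred, obs, metric) {
  if (metric == "AUC") auc(pred, obs) else spearman_rho(pred, obs)
}

#' Internal evaluation by repeated 2-fold cross-validation
#'
#' Per iteration the rows are split at random into two halves; the MAM's
#' predictor set is refitted on each half and predicts the other, and the
#' metric (AUC for presence-absence, Spearman rho for abundance) is
#' computed on the pooled held-out predictions of the iteration. The
#' result is the mean over iterations. Splits whose training half has a
#' single response class are redrawn.
#'
#' @param table observation table.
#' @param response response column name.
#' @param scope predictor names of the selected model (refitted per fold).
#' @param family a [family_spec()].
#' @param n_iter number of cross-validation iterations.
#' @param seed integer seed for the split sequence.
#' @param metric `"AUC"` or `"rho"`; defaults by family link.
#' @return An `evaluation_result` with mode `"IE"` and the per-iteration
#'   values.
#' @export
internal_evaluate <- function(table, response, scope, family,
                              n_iter = 100, seed = 1,
                              metric = NULL) {
  if (is.null(metric)) {
    metric <- if (response_kind(family) == "PA") "AUC" else "rho"
  }
  n <- nrow(table)
  set.seed(seed)
  vals <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    ok <- FALSE
    for (attempt in 1:100) {
      half <- sample(n, floor(n / 2))
      folds <- list(half, setdiff(seq_len(n), half))
      valid <- TRUE
      if (metric == "AUC") {
        for (f in folds) {
          if (length(unique(table[[response]][f])) < 2) valid <- FALSE
        }
      } else {
        for (f in folds) {
          if (stats::sd(table[[response]][f]) == 0) valid <- FALSE
        }
      }
      if (valid) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not draw a valid 50/50 split in 100 attempts ",
           "(iteration ", it, ")")
    }
    pred <- numeric(n)
    failed <- FALSE
    for (j in 1:2) {
      train <- folds[[j]]; test <- folds[[3 - j]]
      m <- tryCatch(
        suppressWarnings(fit_glm(table[train, , drop = FALSE], response,
                                 scope, family)),
        error = function(e) NULL)
      if (is.null(m)) { failed <- TRUE; break }
      pred[test] <- predict(m, table[test, , drop = FALSE])
    }
    vals[it] <- if (failed) NA_real_ else
      eval_metric(pred, table[[response]], metric)
  }
  new_evaluation_result(metric, mean(vals, na.rm = TRUE), "IE",
                        per_iteration = vals,
                        calibration_id = attr(table, "dataset_id"),
                        evaluation_id = attr(table, "dataset_id"))
}

#' External evaluation on an independent data set
#'
#' Fits the predictor set on the calibration table and scores the
#' evaluation table's observations.
#'
#' @param calib_table calibration observation table.
#' @param eval_table evaluation observation table (must provide every
#'   predictor in `scope`).
#' @inheritParams internal_evaluate
#' @return An `evaluation_result` with mode `"EE"`.
#' @export
external_evaluate <- function(calib_table, eval_table, response, scope,
                              family, metric = NULL) {
  if (is.null(metric)) {
    metric <- if (response_kind(family) == "PA") "AUC" else "rho"
  }
  missing <- setdiff(scope, names(eval_table))
  if (length(missing)) {
    stop("evaluation table lacks predictors: ",
         paste(missing, collapse = ", "))
  }
  m <- suppressWarnings(fit_glm(calib_table, response, scope, family))
  pred <- predict(m, eval_table)
  new_evaluation_result(metric,
                        eval_metric(pred, eval_table[[response]], metric),
                        "EE",
                        calibration_id = attr(calib_table, "dataset_id"),
                        evaluation_id = attr(eval_table, "dataset_id"))
}
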