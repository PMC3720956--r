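# Cross-life-stage transferability of abiotic niche models, and asymmetric
# transferability between locations and stages.

#' Life-stage transferability of a calibrated model
#'
#' Applies the fitted linear predictor of a model calibrated on one life
#' stage to the shared point-level abiotic covariates of a target table,
#' and scores the predictions against the target stage's observed
#' responses: AUC for presence-absence, Spearman rho for abundance.
#'
#' @param calib_mam a `fitted_niche_model` (typically the ABIOT MAM of the
#'   calibrating stage).
#' @param target_table observation table of the target stage; must provide
#'   all predictors retained by the calibration MAM.
#' @param response target response column name.
#' @param metric `"AUC"` or `"rho"`; defaults by the calibration family.
#' @return A list of class `transfer_result`: `value` (T), `metric`,
#'   `verdict` (`"pass"`/`"fail"`, see [transfer_verdict()]).
#' @export
stage_transfer <- function(calib_mam, target_table, response,
                           metric = NULL) {
  if (is.null(metric)) {
    metric <- if (response_kind(calib_mam$family) == "PA") "AUC" else "rho"
  }
  missing <- setdiff(calib_mam$predictors, names(target_table))
  if (length(missing)) {
    stop("target table lacks shared predictors: ",
         paste(missing, collapse = ", "))
  }
  pred <- predict(calib_mam, target_table)
  value <- eval_metric(pred, target_table[[response]], metric)
  structure(list(value = value, metric = metric,
                 verdict = transfer_verdict(metric, value),
                 calibration_id = calib_mam$dataset_id,
                 evaluation_id = attr(target_table, "dataset_id")),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("Transferability: %s = %.3f -> %s\n", x$metric, x$value,
              x$verdict))
  invisible(x)
}

#' Transferability verdict
#'
#' Transfer fails when AUC < 0.70 (presence-absence) or rho < 0.40
#' (abundance); boundary values pass.
#'
#' @param metric `"AUC"` or `"rho"`.
#' @param value metric value.
#' @return `"pass"` or `"fail"`.
#' @export
transfer_verdict <- function(metric = c("AUC", "rho"), value) {
  metric <- match.arg(metric)
  threshold <- if (metric == "AUC") 0.70 else 0.40
  if (value < threshold) "fail" else "pass"
}

#' Asymmetric transferability
#'
#' Percentage decrease of the mean transfer metric in the weaker direction
#' relative to the stronger: `AT = (backward - forward) / backward * 100`,
#' where `forward` is the mean metric of the direction under report and
#' `backward` that of the reverse direction. A positive value means
#' models transfer worse in the forward direction. The same operation
#' serves location asymmetry (A to B vs B to A) and stage asymmetry
#' (adult to larva vs larva to adult).
#'
#' @param mean_T_forward mean transfer metric in the reported direction.
#' @param mean_T_backward mean transfer metric in the reverse direction.
#' @return Percentage (signed).
#' @examples
#' asymmetric_transfer(0.752, 0.80)  # 6% decrease
#' @export
asymmetric_transfer <- function(mean_T_forward, mean_T_backward) {
  if (mean_T_backward == 0) {
    stop("asymmetric transferability undefined: zero reference mean")
  }
  (mean_T_backward - mean_T_forward) / mean_T_backward * 100
}
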