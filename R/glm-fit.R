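# GLM calibration: family rules (binomial/quasibinomial for
# presence-absence, negative binomial/Poisson for abundance), bidirectional
# stepwise AIC selection, Nagelkerke R2, per-category explained deviance.

#' Family specification for a niche model
#'
#' Presence-absence responses use logit-link families (binomial,
#' quasibinomial); abundance responses use log-link count families
#' (negative binomial with clumping parameter `k`, or Poisson when
#' aggregation is low).
#'
#' @param family one of `"binomial"`, `"quasibinomial"`, `"poisson"`,
#'   `"negative_binomial"`.
#' @param k clumping parameter; when supplied for a negative-binomial
#'   model it is held fixed, otherwise it is estimated by maximum
#'   likelihood jointly with the coefficients.
#' @param dispersion quasibinomial dispersion estimate (used for QAIC).
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(family = c("binomial", "quasibinomial", "poisson",
                                   "negative_binomial"),
                        k = NULL, dispersion = NULL) {
  family <- match.arg(family)
  if (!is.null(k) && k <= 0) stop("clumping parameter k must be > 0")
  structure(list(family = family,
                 link = if (family %in% c("binomial", "quasibinomial"))
                   "logit" else "log",
                 k = k, dispersion = dispersion),
            class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  cat("Family:", x$family, "(", x$link, "link )")
  if (!is.null(x$k)) cat(", k =", signif(x$k, 4))
  if (!is.null(x$dispersion)) cat(", dispersion =", signif(x$dispersion, 4))
  cat("\n")
  invisible(x)
}

response_kind <- function(family) {
  if (family$family %in% c("binomial", "quasibinomial")) "PA" else "AB"
}

#' Fit a single GLM
#'
#' Maximum-likelihood (or quasi-likelihood) fit by iteratively reweighted
#' least squares. Negative-binomial models estimate the clumping parameter
#' `k` by profile maximum likelihood (via [MASS::glm.nb()]) unless the
#' family spec fixes it. Perfect separation in a presence-absence fit is
#' detected (fitted probabilities numerically 0/1) and flagged; the
#' iteration-capped coefficients are kept.
#'
#' @param table data providing response and predictors.
#' @param response response column name.
#' @param predictors character vector of predictor names; `character(0)`
#'   gives the intercept-only model.
#' @param family a [family_spec()].
#' @param dataset_id,predictor_set optional labels carried into the result.
#' @return An object of class `fitted_niche_model`: coefficients with
#'   standard errors, null and residual deviance, log-likelihood, AIC
#'   (QAIC slot for quasibinomial), the estimated `k`, and the underlying
#'   `glm` fit (for prediction).
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.3), x = rnorm(100))
#' m <- fit_glm(d, "y", "x", family_spec("binomial"))
#' m$aic
#' @export
fit_glm <- function(table, response, predictors, family,
                    dataset_id = NA, predictor_set = NA) {
  stopifnot(inherits(family, "family_spec"))
  rhs <- if (length(predictors) == 0) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(paste(sprintf("`%s`", response), "~", rhs))
  separation <- FALSE
  wh <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
      separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  fit <- switch(family$family,
    binomial = withCallingHandlers(
      stats::glm(fml, data = table, family = stats::binomial()),
      warning = wh),
    quasibinomial = withCallingHandlers(
      stats::glm(fml, data = table, family = stats::quasibinomial()),
      warning = wh),
    poisson = stats::glm(fml, data = table, family = stats::poisson()),
    negative_binomial = {
      if (!is.null(family$k)) {
        stats::glm(fml, data = table,
                   family = MASS::negative.binomial(theta = family$k))
      } else {
        MASS::glm.nb(fml, data = table)
      }
    })
  if (family$family %in% c("binomial", "quasibinomial")) {
    mu <- stats::fitted(fit)
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) separation <- TRUE
  }
  if (!fit$converged && family$family != "negative_binomial" &&
      !separation) {
    stop("GLM did not converge: ", deparse(fml))
  }
  co <- summary(fit)$coefficients
  k_hat <- if (family$family == "negative_binomial") {
    if (!is.null(family$k)) family$k else fit$theta
  } else NULL
  ll <- tryCatch(as.numeric(stats::logLik(fit)), error = function(e) NA_real_)
  aic <- if (family$family == "quasibinomial") NA_real_ else
    tryCatch(stats::AIC(fit), error = function(e) NA_real_)
  out <- list(
    family = family_spec(family$family, k = k_hat,
                         dispersion = if (family$family == "quasibinomial")
                           summary(fit)$dispersion else NULL),
    predictors = predictors,
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, 1], se = co[, 2],
                              row.names = NULL, stringsAsFactors = FALSE),
    null_deviance = fit$null.deviance,
    residual_deviance = fit$deviance,
    loglik = ll,
    aic = aic,
    n = stats::nobs(fit),
    separation = separation,
    response = response,
    predictor_set = predictor_set,
    dataset_id = dataset_id,
    fit = fit)
  class(out) <- "fitted_niche_model"
  out
}

#' @export
print.fitted_niche_model <- function(x, ...) {
  cat("Niche GLM (", x$family$family, "), ", x$response, " ~ ",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else
        "1", "\n", sep = "")
  cat("  n =", x$n, "; deviance", round(x$residual_deviance, 2), "/",
      round(x$null_deviance, 2), "(null); AIC",
      round(x$aic, 2), "\n")
  if (x$separation) cat("  [flag] perfect separation detected\n")
  invisible(x)
}

#' Predict from a fitted niche model
#'
#' @param object a `fitted_niche_model`.
#' @param newdata data.frame providing all retained predictors.
#' @param type `"response"` (probability / expected count) or `"link"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.fitted_niche_model <- function(object, newdata,
                                       type = c("response", "link"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) {
    stop("prediction data lacks predictors: ",
         paste(missing, collapse = ", "))
  }
  as.numeric(stats::predict(object$fit, newdata = newdata, type = type))
}

#' Choose the error family for a response
#'
#' Presence-absence responses use the binomial family; strictly binary
#' (ungrouped) data cannot exhibit estimable overdispersion, so the switch
#' to quasibinomial applies only when the response is grouped and the
#' Pearson dispersion of the binomial fit exceeds the threshold. Abundance
#' responses use the negative binomial; when the estimated clumping
#' parameter `k` is large (weak aggregation, near-equidispersion) the
#' Poisson family is chosen instead.
#'
#' @param table data providing the response.
#' @param response response column name.
#' @param kind `"PA"` or `"AB"`.
#' @param dispersion_threshold quasibinomial switch on the Pearson
#'   dispersion statistic.
#' @param k_threshold Poisson switch on the estimated clumping parameter.
#' @return A [family_spec()]; the trigger value is attached as attribute
#'   `trigger`.
#' @export
choose_family <- function(table, response, kind = c("PA", "AB"),
                          dispersion_threshold = 1.5, k_threshold = 10) {
  kind <- match.arg(kind)
  y <- table[[response]]
  if (kind == "PA") {
    if (!all(y %in% c(0, 1))) {
      fit <- stats::glm(y ~ 1, family = stats::binomial())
      disp <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
      if (is.finite(disp) && disp > dispersion_threshold) {
        return(structure(family_spec("quasibinomial", dispersion = disp),
                         trigger = disp))
      }
    }
    return(structure(family_spec("binomial"), trigger = 1))
  }
  if (stats::var(y) <= mean(y)) {
    warning("response variance <= mean; clumping parameter diverges, ",
            "using Poisson")
    return(structure(family_spec("poisson"), trigger = Inf))
  }
  k_hat <- tryCatch({
    fit <- withCallingHandlers(
      MASS::glm.nb(y ~ 1),
      warning = function(w) invokeRestart("muffleWarning"))
    fit$theta
  }, error = function(e) Inf)
  if (!is.finite(k_hat) || k_hat > k_threshold) {
    structure(family_spec("poisson"), trigger = k_hat)
  } else {
    structure(family_spec("negative_binomial"), trigger = k_hat)
  }
}

# Model-comparison criterion used by the stepwise search: AIC for
# likelihood families, QAIC (-2 logLik / c_hat + 2 p) for quasibinomial,
# with c_hat estimated once from the largest model in scope.
step_criterion <- function(table, response, predictors, family, c_hat) {
  m <- tryCatch(
    suppressWarnings(fit_glm(table, response, predictors, family)),
    error = function(e) NULL)
  if (is.null(m)) return(list(crit = Inf, model = NULL))
  crit <- if (family$family == "quasibinomial") {
    bin <- suppressWarnings(
      fit_glm(table, response, predictors, family_spec("binomial")))
    -2 * bin$loglik / c_hat + 2 * (length(predictors) + 1)
  } else {
    m$aic
  }
  list(crit = crit, model = m)
}

#' Bidirectional stepwise AIC selection
#'
#' Finds the minimal adequate model (MAM) over a candidate scope by
#' bidirectional stepping launched from both endpoints: once from the
#' full-scope model and once from the intercept-only model. At each step
#' every single-term addition and deletion is evaluated and the move with
#' the largest AIC decrease is taken; stepping stops when no move
#' decreases the AIC. The lower-AIC endpoint of the two runs is returned;
#' ties are broken by fewer parameters, then lexicographically by
#' predictor names. Quasibinomial scopes are compared by QAIC and the
#' result is flagged.
#'
#' @param table data.
#' @param response response column name.
#' @param scope candidate predictor names (the post-screening set).
#' @param family a [family_spec()].
#' @return The selected `fitted_niche_model`, with the per-move `trace`
#'   and selection criterion attached.
#' @examples
#' d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
#' d$y <- rbinom(200, 1, plogis(2 * d$x1))
#' m <- stepwise_aic(d, "y", c("x1", "x2"), family_spec("binomial"))
#' m$predictors
#' @export
stepwise_aic <- function(table, response, scope, family) {
  cache <- new.env(parent = emptyenv())
  c_hat <- 1
  if (family$family == "quasibinomial") {
    full_bin <- suppressWarnings(
      fit_glm(table, response, scope, family_spec("binomial")))
    c_hat <- sum(stats::residuals(full_bin$fit, "pearson")^2) /
      full_bin$fit$df.residual
    c_hat <- max(c_hat, 1)
  }
  crit_of <- function(preds) {
    key <- paste0("m:", paste(sort(preds), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- step_criterion(table, response, preds, family, c_hat)
    cache[[key]] <- res
    res
  }
  run <- function(start) {
    current <- sort(start)
    cur <- crit_of(current)
    trace <- list(list(predictors = current, criterion = cur$crit))
    repeat {
      moves <- c(lapply(setdiff(scope, current),
                        function(v) sort(c(current, v))),
                 lapply(current, function(v) setdiff(current, v)))
      if (length(moves) == 0) break
      crits <- vapply(moves, function(m) crit_of(m)$crit, numeric(1))
      sizes <- vapply(moves, length, integer(1))
      keys <- vapply(moves, paste, character(1), collapse = "|")
      ord <- order(crits, sizes, keys)
      best <- ord[1]
      if (!(crits[best] < cur$crit)) break
      current <- moves[[best]]
      cur <- crit_of(current)
      trace[[length(trace) + 1L]] <-
        list(predictors = current, criterion = cur$crit)
    }
    list(predictors = current, crit = cur$crit, model = cur$model,
         trace = trace)
  }
  back <- run(scope)
  fwd <- run(character(0))
  pick <- if (back$crit < fwd$crit) back
    else if (fwd$crit < back$crit) fwd
    else if (length(fwd$predictors) != length(back$predictors)) {
      if (length(fwd$predictors) < length(back$predictors)) fwd else back
    } else if (paste(sort(fwd$predictors), collapse = "|") <=
               paste(sort(back$predictors), collapse = "|")) fwd else back
  mam <- pick$model
  mam$selection_criterion <-
    if (family$family == "quasibinomial") "QAIC" else "AIC"
  mam$criterion_value <- pick$crit
  mam$trace <- list(backward_led = back$trace, forward_led = fwd$trace)
  mam
}

#' Nagelkerke's coefficient of determination
#'
#' The Cox-Snell R2 rescaled so its maximum is 1:
#' `R2 = (1 - exp(-(D0 - D1)/n)) / (1 - exp(-D0/n))`, with `D0` and `D1`
#' the null and residual deviances. Quasibinomial fits use the underlying
#' binomial deviances (numerically identical under IRLS).
#'
#' @param model a `fitted_niche_model`, or a list with elements
#'   `null_deviance`, `residual_deviance`, `n`.
#' @return Value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(model) {
  d0 <- model$null_deviance
  d1 <- model$residual_deviance
  n <- model$n
  if (is.null(n) || n == 0) stop("n = 0: Nagelkerke R2 undefined")
  if (d0 <= 0) stop("null deviance is 0: Nagelkerke R2 undefined")
  num <- 1 - exp(-(d0 - d1) / n)
  den <- 1 - exp(-d0 / n)
  max(0, min(1, num / den))
}

#' Per-category percentage of explained deviance
#'
#' For each abiotic category with predictors retained in the MAM, refits
#' the MAM without that category's predictors; the category's joint
#' contribution is the resulting rise in residual deviance as a percentage
#' of the null deviance. Categories absent from the MAM contribute 0.
#'
#' @param mam a `fitted_niche_model`.
#' @param table the data the MAM was fitted on.
#' @param category_map named character vector mapping predictor names to
#'   categories; defaults to the catalog categories.
#' @return Named numeric vector over COVER, RESISTANCE, SOIL, STRUCTURE
#'   (percent of null deviance; `NA` if a refit fails).
#' @export
category_deviance <- function(mam, table,
                              category_map = NULL) {
  cats <- c("COVER", "RESISTANCE", "SOIL", "STRUCTURE")
  if (is.null(category_map)) {
    category_map <- variable_categories(mam$predictors)
  }
  out <- stats::setNames(rep(0, length(cats)), cats)
  for (cc in cats) {
    in_cat <- mam$predictors[category_map[mam$predictors] == cc]
    if (length(in_cat) == 0) next
    reduced <- tryCatch(
      suppressWarnings(fit_glm(table, mam$response,
                               setdiff(mam$predictors, in_cat),
                               mam$family)),
      error = function(e) NULL)
    out[cc] <- if (is.null(reduced)) NA_real_ else
      (reduced$residual_deviance - mam$residual_deviance) /
        mam$null_deviance * 100
  }
  out
}

#' Calibrate the ABIOT / BIOT / FULL model triplet for one data set
#'
#' Screens the abiotic and biotic candidate sets separately, selects the
#' abiotic-only (ABIOT) and biotic-only (BIOT) minimal adequate models by
#' bidirectional stepwise AIC, then selects the FULL model by stepwise
#' over the union of the predictors retained in the two MAMs.
#'
#' @param table an observation table with `PA`/`AB` responses and
#'   predictor attributes.
#' @param response `"PA"` or `"AB"`.
#' @param family optional [family_spec()]; chosen by [choose_family()]
#'   when omitted.
#' @param p_threshold,cor_threshold,vif_threshold screening thresholds.
#' @return An object of class `model_triplet`: list with `abiot`, `biot`,
#'   `full` fitted models, their Nagelkerke `r2` values, the screening
#'   reports, and the family.
#' @export
fit_model_triplet <- function(table, response, family = NULL,
                              p_threshold = 0.1, cor_threshold = 0.7,
                              vif_threshold = 10) {
  if (is.null(family)) {
    family <- choose_family(table, response, kind = response)
  }
  scr_a <- screen_predictors(table, response, family,
                             candidates = abiotic_vars(table),
                             p_threshold, cor_threshold, vif_threshold)
  scr_b <- screen_predictors(table, response, family,
                             candidates = biotic_vars(table),
                             p_threshold, cor_threshold, vif_threshold)
  abiot <- stepwise_aic(table, response, scr_a$retained, family)
  biot <- stepwise_aic(table, response, scr_b$retained, family)
  full_scope <- union(abiot$predictors, biot$predictors)
  full <- stepwise_aic(table, response, full_scope, family)
  for (nm in c("abiot", "biot", "full")) {
    m <- get(nm)
    m$predictor_set <- toupper(nm)
    m$response <- response
    m$dataset_id <- attr(table, "dataset_id")
    assign(nm, m)
  }
  out <- list(abiot = abiot, biot = biot, full = full,
              r2 = c(ABIOT = nagelkerke_r2(abiot),
                     BIOT = nagelkerke_r2(biot),
                     FULL = nagelkerke_r2(full)),
              aic = c(null = {
                null <- suppressWarnings(
                  fit_glm(table, response, character(0), family))
                null$aic
              }, ABIOT = abiot$aic, BIOT = biot$aic, FULL = full$aic),
              screening = list(abiotic = scr_a, biotic = scr_b),
              family = family, response = response,
              dataset_id = attr(table, "dataset_id"))
  class(out) <- "model_triplet"
  out
}

#' @export
print.model_triplet <- function(x, ...) {
  cat("Model triplet (data set ", x$dataset_id, ", ", x$response, ", ",
      x$family$family, ")\n", sep = "")
  cat(sprintf("  R2: ABIOT %.2f | BIOT %.2f | FULL %.2f\n",
              x$r2["ABIOT"], x$r2["BIOT"], x$r2["FULL"]))
  invisible(x)
}
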