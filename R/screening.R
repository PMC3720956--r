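# Predictor screening: univariate GLM filter, Spearman correlation filter
# with scale competition, sequential VIF dropping.

#' Univariate GLM screening of candidate predictors
#'
#' Fits one single-predictor GLM per candidate and keeps those whose
#' likelihood-ratio test against the intercept-only model gives
#' `p < p_threshold`. Candidates are returned ranked by descending
#' univariate explained deviance, `(D0 - D1) / D0`.
#'
#' @param table an observation table.
#' @param response response column name (`"PA"` or `"AB"`).
#' @param family a [family_spec()] appropriate for the response.
#' @param candidates candidate predictor names; defaults to the table's
#'   abiotic predictors.
#' @param p_threshold retention threshold on the likelihood-ratio p-value.
#' @return A data.frame (one row per candidate, ranked: retained first by
#'   descending explained deviance) with columns `variable`, `p_value`,
#'   `expl_dev`, `retained`, `reason`.
#' @export
univariate_screen <- function(table, response, family,
                              candidates = abiotic_vars(table),
                              p_threshold = 0.1) {
  stopifnot(nrow(table) > 2, response %in% names(table))
  res <- lapply(candidates, function(v) {
    fit <- tryCatch(
      fit_glm(table, response, v, family),
      error = function(e) NULL, warning = function(w) {
        tryCatch(suppressWarnings(fit_glm(table, response, v, family)),
                 error = function(e) NULL)
      })
    if (is.null(fit) || !is.finite(fit$residual_deviance)) {
      return(data.frame(variable = v, p_value = NA_real_,
                        expl_dev = NA_real_, retained = FALSE,
                        reason = "fit-failed", stringsAsFactors = FALSE))
    }
    d0 <- fit$null_deviance
    d1 <- fit$residual_deviance
    p <- stats::pchisq(max(d0 - d1, 0), df = 1, lower.tail = FALSE)
    ed <- if (d0 > 0) max(d0 - d1, 0) / d0 else NA_real_
    data.frame(variable = v, p_value = p, expl_dev = ed,
               retained = is.finite(p) && p < p_threshold,
               reason = if (is.finite(p) && p < p_threshold) "" else
                 "failed-p",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # retained candidates first, by descending explained deviance;
  # lexicographic tie-break for determinism
  ord <- order(!out$retained, -ifelse(is.na(out$expl_dev), -Inf,
                                      out$expl_dev), out$variable)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman correlation filter with scale competition
#'
#' Greedy pass over candidates in rank order (best univariate explained
#' deviance first). A candidate is dropped when (a) a better-ranked scale
#' version of the same multiscale variable has already been retained
#' (scale competition: only the most relevant scale of each cover or
#' structure variable enters the models), or (b) its absolute Spearman
#' rank correlation with any already-retained variable reaches the
#' threshold.
#'
#' @param candidates character vector of candidate names, ranked.
#' @param table the observation table providing the columns.
#' @param threshold drop when `|rho| >=` this value.
#' @param catalog variable catalog supplying the scale groups.
#' @return A data.frame with columns `variable`, `retained`, `reason`,
#'   in candidate order; retained names in `attr(, "retained")`.
#' @export
correlation_filter <- function(candidates, table, threshold = 0.7,
                               catalog = variable_catalog()) {
  retained <- character(0)
  groups_seen <- character(0)
  rows <- vector("list", length(candidates))
  grp <- catalog$scale_group[match(candidates, catalog$name)]
  cat_of <- catalog$category[match(candidates, catalog$name)]
  for (i in seq_along(candidates)) {
    v <- candidates[i]
    x <- table[[v]]
    reason <- ""
    if (is.null(x)) {
      reason <- "missing-column"
    } else if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) {
      reason <- "constant"
    } else if (!is.na(grp[i]) &&
               paste(cat_of[i], grp[i]) %in% groups_seen) {
      reason <- "scale-competition"
    } else {
      for (r in retained) {
        rho <- suppressWarnings(
          stats::cor(x, table[[r]], method = "spearman"))
        if (!is.finite(rho) || abs(rho) >= threshold) {
          reason <- paste0("correlated-with:", r)
          break
        }
      }
    }
    if (reason == "") {
      retained <- c(retained, v)
      if (!is.na(grp[i])) {
        groups_seen <- c(groups_seen, paste(cat_of[i], grp[i]))
      }
    }
    rows[[i]] <- data.frame(variable = v, retained = reason == "",
                            reason = reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "retained") <- retained
  out
}

#' Variance inflation factors by auxiliary OLS regressions
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of
#' determination of the ordinary least-squares regression of predictor
#' `j` on all other predictors. Exact collinearity gives `Inf`.
#'
#' @param table data providing the predictor columns.
#' @param vars predictor names (>= 2 for non-trivial values).
#' @return Named numeric vector of VIFs.
#' @export
vif_values <- function(table, vars) {
  if (length(vars) < 2) {
    return(stats::setNames(rep(1, length(vars)), vars))
  }
  x <- as.matrix(table[, vars, drop = FALSE])
  vapply(seq_along(vars), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((x[, j] - mean(x[, j]))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, vars)
}

#' Sequential VIF dropping
#'
#' Repeatedly computes all VIFs among the retained predictors and drops
#' the single largest while it reaches the threshold; exact collinearity
#' (infinite VIF) is dropped first. Terminates in at most `length(vars)`
#' iterations.
#'
#' @param table data providing the columns.
#' @param vars retained predictor names.
#' @param vif_threshold drop while the maximum VIF is `>=` this value.
#' @return List: `retained` (names), `vifs` (final VIFs), `dropped`
#'   (data.frame of dropped variables and the VIF that removed them).
#' @export
vif_cascade <- function(table, vars, vif_threshold = 10) {
  stopifnot(length(vars) >= 1)
  dropped <- list()
  repeat {
    v <- vif_values(table, vars)
    if (length(vars) <= 1 || max(v) < vif_threshold) break
    worst <- names(v)[which.max(v)]
    dropped[[length(dropped) + 1L]] <-
      data.frame(variable = worst, vif = unname(v[worst]),
                 stringsAsFactors = FALSE)
    vars <- setdiff(vars, worst)
  }
  list(retained = vars, vifs = v,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(variable = character(0), vif = numeric(0)))
}

#' Full screening chain for one model's candidate set
#'
#' Runs [univariate_screen()], [correlation_filter()] and [vif_cascade()]
#' in sequence and assembles a per-variable report.
#'
#' @inheritParams univariate_screen
#' @param cor_threshold Spearman correlation threshold.
#' @param vif_threshold VIF threshold.
#' @param allow,block optional user-supplied allowlist / blocklist applied
#'   before screening (expert knowledge of predictor relevance).
#' @return An object of class `screening_report`: a list with `report`
#'   (per-variable status data.frame), `retained` (final names, ranked)
#'   and `vifs`.
#' @examples
#' sv <- simulate_survey(seed = 1)
#' ds <- assemble_datasets(sv)
#' sc <- screen_predictors(ds$ds1, "PA", family_spec("binomial"))
#' sc$retained
#' @export
screen_predictors <- function(table, response, family,
                              candidates = abiotic_vars(table),
                              p_threshold = 0.1, cor_threshold = 0.7,
                              vif_threshold = 10,
                              allow = NULL, block = NULL) {
  if (!is.null(allow)) candidates <- intersect(candidates, allow)
  if (!is.null(block)) candidates <- setdiff(candidates, block)
  uni <- univariate_screen(table, response, family, candidates,
                           p_threshold)
  ranked <- uni$variable[uni$retained]
  status <- stats::setNames(uni$reason, uni$variable)
  vifs <- stats::setNames(numeric(0), character(0))
  final <- character(0)
  if (length(ranked) > 0) {
    cf <- correlation_filter(ranked, table, cor_threshold)
    for (i in seq_len(nrow(cf))) {
      if (!cf$retained[i]) status[cf$variable[i]] <- cf$reason[i]
    }
    surv <- attr(cf, "retained")
    if (length(surv) > 0) {
      vc <- vif_cascade(table, surv, vif_threshold)
      for (v in vc$dropped$variable) status[v] <- "vif-dropped"
      final <- vc$retained
      vifs <- vc$vifs
    }
  }
  report <- data.frame(
    variable = uni$variable,
    p_value = uni$p_value,
    expl_dev = uni$expl_dev,
    retained = uni$variable %in% final,
    reason = ifelse(uni$variable %in% final, "", status[uni$variable]),
    stringsAsFactors = FALSE)
  out <- list(report = report, retained = final, vifs = vifs,
              thresholds = c(p = p_threshold, rho = cor_threshold,
                             vif = vif_threshold))
  class(out) <- "screening_report"
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening:", sum(x$report$retained), "of", nrow(x$report),
      "candidates retained\n")
  if (length(x$retained)) {
    cat(" ", paste(x$retained, collapse = ", "), "\n")
  }
  invisible(x)
}
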