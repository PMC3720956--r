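# End-to-end orchestration: simulate/ingest -> screen -> fit triplets ->
# evaluate -> transfer -> partition -> residual autocorrelation, with
# tabular reports mirroring the study's result layouts.

biotic_column_registry <- function() {
  c("LARVA_PA", "LARVA_AB", "ADULT_PA", "ADULT_AB",
    "CONGEN_ADULT_PA", "CONGEN_ADULT_AB",
    "CONGEN_LARVA_PA", "CONGEN_LARVA_AB", "NEIGH_LARVA_AB")
}

meta_column_registry <- function() {
  c("unit_id", "location", "point_id", "habitat_type", "x", "y",
    "PA", "AB")
}

#' Write an observation table to CSV
#'
#' Writes the rows as CSV (full double precision) and the table's
#' metadata (data-set id, location, stage, scale, predictor-role column
#' lists) as a JSON sidecar `<path>.json`, so that
#' [read_observation_table()] round-trips the object exactly.
#'
#' @param table an observation table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(table, path) {
  df <- as.data.frame(table)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  meta <- list(dataset_id = attr(table, "dataset_id"),
               location = attr(table, "location"),
               stage = attr(table, "stage"),
               sampling_scale = attr(table, "sampling_scale"),
               abiotic = attr(table, "abiotic"),
               biotic = attr(table, "biotic"),
               double_columns = names(df)[vapply(df, is.double,
                                                 logical(1))])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an observation table from CSV
#'
#' Validates every column name against the variable catalog and the
#' biotic/metadata registries; unknown columns are an error. Rows with
#' missing values are dropped with a message.
#'
#' @param path CSV path written by [write_observation_table()] (the JSON
#'   sidecar is read when present).
#' @return An observation table.
#' @export
read_observation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- c(meta_column_registry(), variable_catalog()$name,
             biotic_column_registry())
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    stop("unregistered columns: ", paste(unknown, collapse = ", "))
  }
  n_miss <- sum(!stats::complete.cases(df))
  if (n_miss > 0) {
    message("dropping ", n_miss, " rows with missing values")
    df <- df[stats::complete.cases(df), , drop = FALSE]
  }
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    for (col in intersect(meta$double_columns, names(df))) {
      df[[col]] <- as.double(df[[col]])
    }
    return(new_observation_table(df, meta$dataset_id, meta$location,
                                 meta$stage, meta$sampling_scale,
                                 meta$abiotic, meta$biotic))
  }
  abio <- intersect(names(df), variable_catalog()$name)
  bio <- intersect(names(df), biotic_column_registry())
  new_observation_table(df, NA, df$location[1], NA, NA, abio, bio)
}

#' Configuration of a full analysis run
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param design a [survey_design()].
#' @param truth a [synthetic_truth()].
#' @param datasets optional pre-built list of observation tables
#'   (csv-ingest mode); when supplied, `design`/`truth` are ignored.
#' @param cv_iter internal-evaluation iterations (0 skips the stage).
#' @param n_perm Moran permutations (0 skips the stage).
#' @param p_threshold,cor_threshold,vif_threshold screening thresholds.
#' @param dispersion_threshold,k_threshold family-switch thresholds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, design = survey_design(),
                       truth = synthetic_truth(), datasets = NULL,
                       cv_iter = 100, n_perm = 1000,
                       p_threshold = 0.1, cor_threshold = 0.7,
                       vif_threshold = 10,
                       dispersion_threshold = 1.5, k_threshold = 10) {
  stopifnot(p_threshold > 0, cor_threshold > 0, vif_threshold > 0,
            cv_iter >= 0, n_perm >= 0)
  structure(list(seed = seed, design = design, truth = truth,
                 datasets = datasets, cv_iter = cv_iter, n_perm = n_perm,
                 p_threshold = p_threshold, cor_threshold = cor_threshold,
                 vif_threshold = vif_threshold,
                 dispersion_threshold = dispersion_threshold,
                 k_threshold = k_threshold),
            class = "run_config")
}

#' Run the full life-stage niche-modelling analysis
#'
#' Executes every stage for all data sets and both responses: simulate
#' (or ingest) the eight observation tables; screen abiotic and biotic
#' candidates; calibrate the ABIOT/BIOT/FULL minimal adequate models;
#' compute Nagelkerke R-squared and AIC tables, per-category explained
#' deviance of the ABIOT MAMs; internal evaluation of ABIOT and BIOT
#' MAMs, external (cross-location) evaluation of ABIOT MAMs; life-stage
#' transferability of the ABIOT MAMs (adult and larva at the 50 cm scale,
#' per location) with location and stage asymmetries; hierarchical
#' partitioning of the R-squared triplets; and Moran's I permutation
#' tests on the residuals of all ABIOT and BIOT MAMs with Holm
#' correction.
#'
#' @param config a [run_config()].
#' @return An object of class `stageniche_run`: list with `r2_table`,
#'   `aic_table`, `coefficients`, `category_deviance`, `evaluation`,
#'   `transfer`, `partition_summaries`, `moran`, `triplets`, `datasets`,
#'   `config`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  datasets <- config$datasets
  if (is.null(datasets)) {
    sv <- simulate_survey(config$design, config$truth, seed = config$seed)
    datasets <- assemble_datasets(sv)
  }
  triplets <- list()
  r2_rows <- list(); aic_rows <- list(); coef_rows <- list()
  cat_rows <- list(); eval_rows <- list()
  moran_models <- list(); moran_tables <- list()

  for (ds_name in names(datasets)) {
    tab <- datasets[[ds_name]]
    ds_id <- attr(tab, "dataset_id")
    for (resp in c("PA", "AB")) {
      trip <- fit_model_triplet(tab, resp,
                                p_threshold = config$p_threshold,
                                cor_threshold = config$cor_threshold,
                                vif_threshold = config$vif_threshold)
      key <- paste0(ds_name, "_", resp)
      triplets[[key]] <- trip
      r2_rows[[key]] <- data.frame(
        dataset = ds_id, response = resp,
        ABIOT = trip$r2["ABIOT"], BIOT = trip$r2["BIOT"],
        FULL = trip$r2["FULL"],
        best = c("ABIOT", "BIOT", "FULL")[which.max(trip$r2)],
        row.names = NULL)
      aic_rows[[key]] <- data.frame(
        dataset = ds_id, response = resp,
        null = trip$aic["null"], ABIOT = trip$aic["ABIOT"],
        BIOT = trip$aic["BIOT"], FULL = trip$aic["FULL"],
        best = c("null", "ABIOT", "BIOT", "FULL")[which.min(trip$aic)],
        row.names = NULL)
      for (set in c("abiot", "biot", "full")) {
        m <- trip[[set]]
        if (nrow(m$coefficients)) {
          coef_rows[[paste(key, set)]] <- cbind(
            data.frame(dataset = ds_id, response = resp,
                       predictor_set = toupper(set)),
            m$coefficients)
        }
      }
      if (length(trip$abiot$predictors)) {
        cd <- category_deviance(trip$abiot, tab)
        cat_rows[[key]] <- cbind(
          data.frame(dataset = ds_id, response = resp), t(cd))
      }
      if (config$cv_iter > 0) {
        for (set in c("abiot", "biot")) {
          m <- trip[[set]]
          ev <- tryCatch(
            internal_evaluate(tab, resp, m$predictors, trip$family,
                              n_iter = config$cv_iter,
                              seed = config$seed + 1000 * ds_id),
            error = function(e) NULL)
          if (!is.null(ev)) {
            eval_rows[[paste(key, set, "IE")]] <- data.frame(
              dataset = ds_id, response = resp,
              predictor_set = toupper(set), mode = "IE",
              metric = ev$metric, value = ev$value, band = ev$band,
              calibration = ds_id, evaluation = ds_id)
          }
        }
      }
      moran_models[[paste(key, "ABIOT")]] <- trip$abiot
      moran_tables[[paste(key, "ABIOT")]] <- tab
      moran_models[[paste(key, "BIOT")]] <- trip$biot
      moran_tables[[paste(key, "BIOT")]] <- tab
    }
  }

  # external evaluation of the ABIOT MAMs: cross-location pairs
  n_loc <- length(unique(vapply(datasets, attr, "", "location")))
  if (n_loc == 2) {
    pair_of <- function(id) if (id %% 2 == 1) id + 1 else id - 1
    for (key in names(triplets)) {
      trip <- triplets[[key]]
      other_id <- pair_of(trip$dataset_id)
      other <- datasets[[paste0("ds", other_id)]]
      if (is.null(other) || length(trip$abiot$predictors) == 0) next
      calib <- datasets[[paste0("ds", trip$dataset_id)]]
      ev <- tryCatch(
        external_evaluate(calib, other, trip$response,
                          trip$abiot$predictors, trip$family),
        error = function(e) NULL)
      if (!is.null(ev)) {
        eval_rows[[paste(key, "abiot EE")]] <- data.frame(
          dataset = trip$dataset_id, response = trip$response,
          predictor_set = "ABIOT", mode = "EE", metric = ev$metric,
          value = ev$value, band = ev$band,
          calibration = trip$dataset_id, evaluation = other_id)
      }
    }
  }

  transfer <- run_transfer_stage(triplets, datasets)

  r2_table <- do.call(rbind, r2_rows); rownames(r2_table) <- NULL
  aic_table <- do.call(rbind, aic_rows); rownames(aic_table) <- NULL
  parts <- partition_table(r2_table[, c("dataset", "response", "ABIOT",
                                        "BIOT", "FULL")])
  partition_summaries <- list(
    all = summarize_partitions(parts, "all"),
    location = summarize_partitions(parts, "location"),
    scale = summarize_partitions(parts, "scale"),
    stage = summarize_partitions(parts, "stage"))

  moran <- if (config$n_perm > 0) {
    moran_report(moran_models, moran_tables, n_perm = config$n_perm,
                 seed = config$seed)
  } else NULL

  out <- list(
    r2_table = r2_table,
    aic_table = aic_table,
    coefficients = if (length(coef_rows)) {
      x <- do.call(rbind, coef_rows); rownames(x) <- NULL; x
    } else NULL,
    category_deviance = if (length(cat_rows)) {
      x <- do.call(rbind, cat_rows); rownames(x) <- NULL; x
    } else NULL,
    evaluation = if (length(eval_rows)) {
      x <- do.call(rbind, eval_rows); rownames(x) <- NULL; x
    } else NULL,
    transfer = transfer,
    partitions = parts,
    partition_summaries = partition_summaries,
    moran = moran,
    triplets = triplets,
    datasets = datasets,
    config = config)
  class(out) <- "stageniche_run"
  out
}

# Life-stage transferability of the ABIOT MAMs between the adult (trap)
# and larval 50x50 cm data sets of each location, plus the location and
# stage asymmetries of the external / transfer metrics.
run_transfer_stage <- function(triplets, datasets) {
  locs <- unique(vapply(datasets, attr, "", "location"))
  rows <- list()
  for (li in seq_along(locs)) {
    adult_id <- li          # data sets 1..n_loc are the adult tables
    larva_id <- 4 + li      # 50x50 cm larval tables
    adult_tab <- datasets[[paste0("ds", adult_id)]]
    larva_tab <- datasets[[paste0("ds", larva_id)]]
    if (is.null(adult_tab) || is.null(larva_tab)) next
    for (resp in c("PA", "AB")) {
      a_trip <- triplets[[paste0("ds", adult_id, "_", resp)]]
      l_trip <- triplets[[paste0("ds", larva_id, "_", resp)]]
      if (is.null(a_trip) || is.null(l_trip)) next
      for (dir in c("adult_to_larva", "larva_to_adult")) {
        mam <- if (dir == "adult_to_larva") a_trip$abiot else l_trip$abiot
        target <- if (dir == "adult_to_larva") larva_tab else adult_tab
        if (length(mam$predictors) == 0) next
        tr <- tryCatch(stage_transfer(mam, target, resp),
                       error = function(e) NULL)
        if (is.null(tr)) next
        rows[[paste(locs[li], resp, dir)]] <- data.frame(
          location = locs[li], response = resp, direction = dir,
          metric = tr$metric, value = tr$value, verdict = tr$verdict,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(list(table = NULL, at_stage = NULL))
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  at_stage <- lapply(split(tab, tab$metric), function(d) {
    fwd <- mean(d$value[d$direction == "larva_to_adult"])
    bwd <- mean(d$value[d$direction == "adult_to_larva"])
    if (!is.finite(fwd) || !is.finite(bwd) || bwd == 0) return(NULL)
    data.frame(metric = d$metric[1],
               mean_adult_to_larva = bwd, mean_larva_to_adult = fwd,
               at_percent = asymmetric_transfer(fwd, bwd))
  })
  at_stage <- do.call(rbind, at_stage)
  if (!is.null(at_stage)) rownames(at_stage) <- NULL
  list(table = tab, at_stage = at_stage)
}

# Location asymmetry of the external-evaluation metrics of a run: the
# percentage decrease of the mean metric when models calibrated in the
# first location are applied to the second, relative to the reverse.
#' Location asymmetry of external-evaluation accuracy
#'
#' @param run a `stageniche_run` whose evaluation stage includes EE rows.
#' @return data.frame per metric with the direction means and the
#'   asymmetric-transferability percentage (positive: models transfer
#'   worse from the first location to the second).
#' @export
at_location <- function(run) {
  ev <- run$evaluation
  ev <- ev[ev$mode == "EE", , drop = FALSE]
  if (is.null(ev) || nrow(ev) == 0) return(NULL)
  out <- lapply(split(ev, ev$metric), function(d) {
    a_to_b <- mean(d$value[d$calibration %% 2 == 1])
    b_to_a <- mean(d$value[d$calibration %% 2 == 0])
    data.frame(metric = d$metric[1], mean_A_to_B = a_to_b,
               mean_B_to_A = b_to_a,
               at_percent = asymmetric_transfer(a_to_b, b_to_a))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.stageniche_run <- function(x, ...) {
  cat("stageniche run:", nrow(x$r2_table), "model triplets\n")
  print(x$r2_table, digits = 3)
  invisible(x)
}

#' Write the reports of a run to a directory
#'
#' Serializes the run's result tables: `table3_style.tsv` (Nagelkerke
#' R-squared per model set), `table4_style.tsv` (AIC), coefficient and
#' category-deviance TSVs, evaluation, transfer, partition and Moran
#' tables, and a JSON bundle of the headline tables.
#'
#' @param run a `stageniche_run`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wtsv(run$r2_table[, c("dataset", "response", "ABIOT", "BIOT", "FULL")],
       "table3_style.tsv")
  wtsv(run$aic_table, "table4_style.tsv")
  wtsv(run$coefficients, "coefficients.tsv")
  wtsv(run$category_deviance, "category_deviance.tsv")
  wtsv(run$evaluation, "evaluation.tsv")
  wtsv(run$partitions, "partition.tsv")
  if (!is.null(run$transfer$table)) wtsv(run$transfer$table, "transfer.tsv")
  if (!is.null(run$moran)) wtsv(run$moran, "moran.tsv")
  bundle <- list(r2 = run$r2_table, aic = run$aic_table,
                 partition_summaries = run$partition_summaries,
                 transfer = run$transfer, moran = run$moran)
  jsonlite::write_json(bundle, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
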