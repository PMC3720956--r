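# Hierarchical partitioning of explanatory power into pure-abiotic,
# pure-biotic and joint components, and the grouped mean +/- SD summaries.

#' Partition an (ABIOT, BIOT, FULL) R-squared triplet
#'
#' Hierarchical partitioning over two predictor sets:
#' `pure_abiotic = R2_FULL - R2_BIOT`, `pure_biotic = R2_FULL - R2_ABIOT`,
#' `joint = R2_ABIOT + R2_BIOT - R2_FULL`. The three components sum to
#' `R2_FULL` exactly. Components are not clipped at zero: with rounded
#' inputs a component may come out slightly negative, and values below
#' -0.01 are flagged with a warning rather than corrected, so that the
#' additive identity is preserved.
#'
#' @param r2_abiot,r2_biot,r2_full Nagelkerke R-squared of the
#'   abiotic-only, biotic-only and combined models, each in `[0, 1]`.
#' @return A list of class `partition_triple` with elements
#'   `pure_abiotic`, `pure_biotic`, `joint`.
#' @examples
#' partition_r2(0.73, 0.53, 0.76)
#' @export
partition_r2 <- function(r2_abiot, r2_biot, r2_full) {
  vals <- c(r2_abiot, r2_biot, r2_full)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("R2 inputs must lie in [0, 1]")
  }
  out <- list(pure_abiotic = r2_full - r2_biot,
              pure_biotic = r2_full - r2_abiot,
              joint = r2_abiot + r2_biot - r2_full)
  low <- unlist(out) < -0.01
  if (any(low)) {
    warning("partition component(s) below -0.01: ",
            paste(names(out)[low], collapse = ", "),
            " (inconsistent or heavily rounded inputs)")
  }
  class(out) <- "partition_triple"
  out
}

#' @export
print.partition_triple <- function(x, ...) {
  cat(sprintf("pure abiotic %.3f | pure biotic %.3f | joint %.3f\n",
              x$pure_abiotic, x$pure_biotic, x$joint))
  invisible(x)
}

#' Partition every row of an R-squared table
#'
#' @param r2_table data.frame with columns `dataset`, `response`, `ABIOT`,
#'   `BIOT`, `FULL` (one row per data set and response).
#' @return The input with `pure_abiotic`, `pure_biotic`, `joint` columns
#'   appended.
#' @export
partition_table <- function(r2_table) {
  need <- c("dataset", "response", "ABIOT", "BIOT", "FULL")
  if (!all(need %in% names(r2_table))) {
    stop("r2_table must have columns ", paste(need, collapse = ", "))
  }
  parts <- lapply(seq_len(nrow(r2_table)), function(i) {
    p <- partition_r2(r2_table$ABIOT[i], r2_table$BIOT[i],
                      r2_table$FULL[i])
    data.frame(pure_abiotic = p$pure_abiotic,
               pure_biotic = p$pure_biotic, joint = p$joint)
  })
  cbind(r2_table, do.call(rbind, parts))
}

#' Grouped mean and SD of partition components
#'
#' Summarizes partitioned triplets as arithmetic mean and sample (n - 1)
#' standard deviation per component, over all rows or grouped by
#' location (odd data-set ids = first location), sampling scale, or life
#' stage.
#'
#' @param parts output of [partition_table()] (or any data.frame with
#'   `dataset`, `response` and component columns).
#' @param grouping one of `"all"`, `"location"`, `"scale"`, `"stage"`.
#' @return data.frame with columns `group`, `component`, `mean`, `sd`,
#'   `n`.
#' @examples
#' r2 <- read_r2_table(system.file("extdata", "table3_r2.csv",
#'                                 package = "stageniche"))
#' summarize_partitions(partition_table(r2), "all")
#' @export
summarize_partitions <- function(parts,
                                 grouping = c("all", "location", "scale",
                                              "stage")) {
  grouping <- match.arg(grouping)
  grp <- switch(grouping,
    all = rep("all", nrow(parts)),
    location = ifelse(parts$dataset %% 2 == 1, "A", "B"),
    scale = c("trap", "trap", "1m", "1m", "50cm", "50cm", "25cm",
              "25cm")[parts$dataset],
    stage = ifelse(parts$dataset <= 2, "adult", "larva"))
  comps <- c("pure_abiotic", "pure_biotic", "joint")
  rows <- list()
  for (g in unique(grp)) {
    sel <- parts[grp == g, , drop = FALSE]
    if (nrow(sel) == 0) {
      warning("empty group ", g, " omitted")
      next
    }
    for (cc in comps) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = cc,
        mean = mean(sel[[cc]]),
        sd = if (nrow(sel) >= 2) stats::sd(sel[[cc]]) else NA_real_,
        n = nrow(sel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an (ABIOT, BIOT, FULL) R-squared table from CSV
#'
#' The packaged fixture `table3_r2.csv` holds the published R-squared
#' triplets of the tiger-beetle case study: 8 data sets x 2 responses.
#'
#' @param path CSV path with columns `dataset`, `response`, `ABIOT`,
#'   `BIOT`, `FULL`.
#' @return data.frame.
#' @export
read_r2_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset", "response", "ABIOT", "BIOT", "FULL")
  if (!all(need %in% names(out))) {
    stop("expected columns ", paste(need, collapse = ", "))
  }
  out
}
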