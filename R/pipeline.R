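#' Pipeline run configuration
#'
#' Collects the analysis settings: category size window (default 10-999
#' members), negative subsampling ratio (default 1:4), the fixed 4-fold
#' rotation, recall levels for the precision summaries, and the inclusive
#' 0.75 selection thresholds for high-precision categories and gene-function
#' predictions.
#'
#' @param min_size,max_size inclusive category size window.
#' @param neg_ratio maximum negative:positive ratio.
#' @param k number of folds (fixed at 4 by the rotation scheme).
#' @param recall_levels recall levels for precision-at-recall summaries.
#' @param prec_threshold category selection threshold on mean
#'   precision-at-40.
#' @param gene_prec_threshold prediction selection threshold on mean
#'   gene-precision.
#' @param imputation missing-value treatment, `"zero"` or `"row_mean"`.
#' @param group_duplicates co-assign duplicate clone rows to one fold.
#' @param seed master seed; per-category seeds are derived from it and the
#'   term id, so results for one category do not depend on which other
#'   categories run.
#' @return A `run_config` list.
#' @export
run_config <- function(min_size = 10L, max_size = 999L, neg_ratio = 4L,
                       k = 4L, recall_levels = c(0.2, 0.3, 0.4),
                       prec_threshold = 0.75, gene_prec_threshold = 0.75,
                       imputation = c("zero", "row_mean"),
                       group_duplicates = FALSE, seed = 1L) {
  if (k != 4L) stop("the rotation scheme requires k = 4")
  stopifnot(prec_threshold >= 0, prec_threshold <= 1,
            gene_prec_threshold >= 0, gene_prec_threshold <= 1)
  structure(list(min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 neg_ratio = as.integer(neg_ratio), k = 4L,
                 recall_levels = recall_levels,
                 prec_threshold = prec_threshold,
                 gene_prec_threshold = gene_prec_threshold,
                 imputation = match.arg(imputation),
                 group_duplicates = isTRUE(group_duplicates),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run one category through the rotation cross-validation
#'
#' Task building (negative subsample), stratified partition, 12-arrangement
#' rotation, and the precision / gene-precision summaries, all seeded from
#' the derived per-category seed.
#'
#' @param term_id category identifier.
#' @param annotations an [annotation_table].
#' @param matrix an [expression_matrix] (missing cells allowed; imputed
#'   internally per the config).
#' @param config a [run_config()].
#' @return The [summarize_category()] result, with the `probability_table`
#'   and task attached as `prob_table` and `task`.
#' @export
run_category <- function(term_id, annotations, matrix, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed_c <- derive_seed(config$seed, term_id)
  task <- build_category_task(term_id, annotations, matrix,
                              ratio = config$neg_ratio, seed = seed_c,
                              min_positives = config$min_size)
  partition <- stratified_partition(task, k = config$k, seed = seed_c + 1L,
                                    group_duplicates = config$group_duplicates,
                                    gene_ids = matrix$gene_ids)
  features <- impute_missing(matrix, config$imputation)$values
  prob_table <- rotation_cv(task, partition, features)
  out <- summarize_category(prob_table, recall_levels = config$recall_levels,
                            term_id = term_id, gene_ids = matrix$gene_ids)
  out$prob_table <- prob_table
  out$task <- task
  out$partition <- partition
  out
}

#' Run the full prediction pipeline
#'
#' Selects eligible categories by size, runs each through the rotation
#' cross-validation independently, stacks the performance and gene-precision
#' tables, selects high-precision categories and gene-function predictions
#' at the configured thresholds, and (optionally) writes the run artifacts.
#' A category whose run fails is logged and skipped; the run continues.
#'
#' @param matrix an [expression_matrix].
#' @param annotations an [annotation_table].
#' @param config a [run_config()].
#' @param terms optional character vector restricting the run to these
#'   category ids (still subject to the size filter).
#' @param outdir optional output directory; when given, writes
#'   `task_manifest.tsv`, `performance.tsv`, `probabilities.tsv`,
#'   `gene_precision.tsv`, `predictions.tsv`, `summary.json`, `run_log.txt`.
#' @return A `pipeline_result` list: `categories` (selected size table),
#'   `performance`, `gene_precision`, `high_precision`, `predictions`,
#'   `coverage`, `skipped` (data frame term_id/reason), `config`, and
#'   `results` (per-category [run_category()] outputs).
#' @export
run_pipeline <- function(matrix, annotations, config = run_config(),
                         terms = NULL, outdir = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(annotations, "annotation_table"),
            inherits(config, "run_config"))
  t0 <- Sys.time()
  represented <- unique(matrix$gene_ids[matrix$gene_ids != "UNMAPPED"])
  cats <- select_categories(annotations, represented,
                            min_size = config$min_size,
                            max_size = config$max_size)
  log_lines <- c(sprintf("master seed: %d", config$seed),
                 sprintf("represented genes: %d", length(represented)),
                 sprintf("eligible categories: %d", nrow(cats)))
  if (!is.null(terms)) {
    dropped <- setdiff(terms, cats$term_id)
    if (length(dropped)) {
      log_lines <- c(log_lines, sprintf(
        "requested category outside the size window, skipped: %s",
        paste(dropped, collapse = ", ")))
    }
    cats <- cats[cats$term_id %in% terms, , drop = FALSE]
  }
  results <- list()
  skipped <- data.frame(term_id = character(0), reason = character(0))
  for (term in cats$term_id) {
    res <- tryCatch(run_category(term, annotations, matrix, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(term_id = term, reason = conditionMessage(res)))
      log_lines <- c(log_lines, sprintf("SKIP %s: %s", term,
                                        conditionMessage(res)))
    } else {
      results[[term]] <- res
      log_lines <- c(log_lines, sprintf(
        "OK %s: n_pos=%d n_neg=%d n_unlabeled=%d seed=%d", term,
        length(res$task$positives), length(res$task$negatives),
        length(res$task$unlabeled), res$task$seed))
    }
  }
  performance <- do.call(rbind, c(lapply(results, `[[`, "performance"),
                                  make.row.names = FALSE))
  gene_precision <- do.call(rbind, c(lapply(results, `[[`, "gene_precision"),
                                     make.row.names = FALSE))
  if (is.null(performance)) performance <- data.frame()
  if (is.null(gene_precision)) gene_precision <- data.frame()
  high_precision <- if (nrow(performance)) {
    select_high_precision_categories(performance,
                                     threshold = config$prec_threshold)
  } else performance
  predictions <- if (nrow(gene_precision)) {
    select_predictions(gene_precision, threshold = config$gene_prec_threshold)
  } else gene_precision
  annotated_genes <- unique(annotations$gene_id)
  n_unann <- length(setdiff(represented, annotated_genes))
  n_pred_genes <- length(unique(predictions$gene_id))
  coverage <- list(
    unannotated = coverage_stats(n_unann, length(represented)),
    predicted = if (n_unann > 0) coverage_stats(n_pred_genes, n_unann) else NULL)
  log_lines <- c(log_lines, sprintf(
    "high-precision categories: %d; predictions: %d (for %d genes); elapsed %.1fs",
    nrow(high_precision), nrow(predictions), n_pred_genes,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out <- structure(
    list(categories = cats, performance = performance,
         gene_precision = gene_precision, high_precision = high_precision,
         predictions = predictions, coverage = coverage, skipped = skipped,
         config = config, results = results, log = log_lines),
    class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(out, matrix, outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d categories run (%d skipped), %d high-precision, %d predictions\n",
    length(x$results), nrow(x$skipped), nrow(x$high_precision),
    nrow(x$predictions)))
  invisible(x)
}

tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write pipeline artifacts to a directory
#'
#' @param result a `pipeline_result`.
#' @param matrix the [expression_matrix] the run used (for the task
#'   manifest).
#' @param outdir output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, matrix, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tasks <- lapply(result$results, `[[`, "task")
  if (length(tasks)) {
    write_task_manifest(tasks, file.path(outdir, "task_manifest.tsv"))
  }
  tsv(result$performance, file.path(outdir, "performance.tsv"))
  probs <- do.call(rbind, c(lapply(names(result$results), function(term) {
    lab <- result$results[[term]]$prob_table$labeled
    data.frame(term_id = term, gene_id = matrix$gene_ids[lab$row],
               role = ifelse(lab$label == 1, "labeled_pos", "labeled_neg"),
               test_fold = lab$test_fold, p_arr1 = lab$p1, p_arr2 = lab$p2,
               p_arr3 = lab$p3, p_mean = lab$p_mean)
  }), make.row.names = FALSE))
  if (!is.null(probs)) tsv(probs, file.path(outdir, "probabilities.tsv"))
  tsv(result$gene_precision, file.path(outdir, "gene_precision.tsv"))
  tsv(result$predictions, file.path(outdir, "predictions.tsv"))
  summary <- list(
    n_categories = length(result$results),
    n_skipped = nrow(result$skipped),
    n_high_precision = nrow(result$high_precision),
    n_predictions = nrow(result$predictions),
    n_predicted_genes = length(unique(result$predictions$gene_id)),
    coverage = result$coverage,
    seed = result$config$seed)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(result$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
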