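#' Select high-precision categories
#'
#' Keeps categories whose four-fold mean precision at the chosen recall level
#' reaches the threshold (inclusive: a category at exactly the threshold is
#' kept), sorted by decreasing precision.
#'
#' @param performances data frame of category performance rows (as from
#'   [summarize_category()], stacked).
#' @param threshold inclusive lower bound on mean precision, default 0.75.
#' @param column name of the mean-precision column, default `"prec40_mean"`.
#' @return The qualifying subset of `performances`, sorted descending.
#' @export
select_high_precision_categories <- function(performances, threshold = 0.75,
                                             column = "prec40_mean") {
  if (!column %in% names(performances)) stop("no column ", column)
  keep <- performances[[column]] >= threshold
  out <- performances[keep, , drop = FALSE]
  out <- out[order(-out[[column]], out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select gene-function predictions
#'
#' Emits every (unlabeled gene, category) pair whose mean gene-precision
#' score reaches the threshold (inclusive). A gene may qualify in several
#' categories and then yields several prediction records. Rows describe
#' genes with no GO-BP annotation, so no emitted prediction restates a known
#' annotation.
#'
#' @param gene_records data frame of gene-precision records (as from
#'   [summarize_category()], stacked over categories).
#' @param threshold inclusive lower bound on `gp_mean`, default 0.75.
#' @return The qualifying subset, sorted by decreasing `gp_mean`.
#' @export
select_predictions <- function(gene_records, threshold = 0.75) {
  if (nrow(gene_records) == 0L) return(gene_records)
  out <- gene_records[gene_records$gp_mean >= threshold, , drop = FALSE]
  out <- out[order(-out$gp_mean, out$term_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage percentage with reporting-style rounding
#'
#' `100 * numerator / denominator`, with the integer report rounding half
#' away from zero; the exact ratio is retained alongside.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return List: `percent` (integer as reported), `percent_exact`, `ratio`.
#' @export
coverage_stats <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  ratio <- numerator / denominator
  list(percent = as.integer(round_half_up(100 * ratio)),
       percent_exact = 100 * ratio, ratio = ratio)
}

#' Read a FISH concordance table
#'
#' TSV with columns `gene_id`, `sample_id`, `fish_match` (`+`, `-`, or empty
#' when the gene has no image in the FISH database), `gene_precision`,
#' `prob_score`.
#'
#' @param path path to the table.
#' @return Data frame with those columns.
#' @export
load_concordance_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("gene_id", "sample_id", "fish_match", "gene_precision", "prob_score")
  if (!all(need %in% names(df))) {
    stop("concordance table must have columns: ", paste(need, collapse = ", "))
  }
  df$fish_match[is.na(df$fish_match)] <- ""
  if (!all(df$fish_match %in% c("+", "-", ""))) {
    stop("fish_match entries must be '+', '-' or empty")
  }
  df$gene_precision <- as.numeric(df$gene_precision)
  df$prob_score <- as.numeric(df$prob_score)
  df
}

#' Tally FISH concordance marks
#'
#' Counts the predicted category members whose in-situ hybridization pattern
#' matched known members (`+`) among all members with an image in the FISH
#' database (`+` or `-`).
#'
#' @param table data frame with a `fish_match` column of `+` / `-` / empty
#'   marks (see [load_concordance_table()]).
#' @return List: `n_plus`, `n_marked`, `fraction`, and `percent` (rounded as
#'   reported).
#' @export
fish_concordance_summary <- function(table) {
  marks <- table$fish_match
  n_plus <- sum(marks == "+")
  n_marked <- sum(marks %in% c("+", "-"))
  if (n_marked == 0L) stop("no marked rows; concordance undefined")
  frac <- n_plus / n_marked
  list(n_plus = n_plus, n_marked = n_marked, fraction = frac,
       percent = as.integer(round_half_up(100 * frac)))
}
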