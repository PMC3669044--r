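#' Select GO-BP categories by represented size
#'
#' A category enters the analysis iff the number of represented genes
#' annotated to it lies in a size window (default 10 to 999 inclusive).
#' Counts are over distinct gene ids present in `represented_genes`, not over
#' clone rows.
#'
#' @param annotations an [annotation_table].
#' @param represented_genes character vector of gene ids present on the
#'   array.
#' @param min_size,max_size inclusive bounds on represented member count.
#' @return Data frame `term_id`, `n_members`, sorted by decreasing size then
#'   term id.
#' @export
select_categories <- function(annotations, represented_genes,
                              min_size = 10L, max_size = 999L) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (min_size > max_size) stop("min_size > max_size")
  if (length(represented_genes) == 0L) stop("represented_genes is empty")
  represented_genes <- unique(as.character(represented_genes))
  ann <- annotations[annotations$gene_id %in% represented_genes, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(term_id = character(0), n_members = integer(0)))
  }
  counts <- table(ann$term_id)
  keep <- counts >= min_size & counts <= max_size
  out <- data.frame(term_id = names(counts)[keep],
                    n_members = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_members, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build one category's binary classification task
#'
#' Positives are all expression rows whose gene is annotated to `term_id`.
#' The negative pool is every row whose gene carries at least one GO-BP
#' annotation but not this term; a subset of up to `ratio` times the number
#' of positive rows is drawn uniformly without replacement (class imbalance
#' control, default positive:negative = 1:4). Genes with no GO-BP annotation
#' at all have unknown class: their rows go to `unlabeled` and are scored,
#' never trained on. Rows with the sentinel gene id from [map_ids()] are
#' dropped from the task entirely.
#'
#' @param term_id GO-BP term identifier.
#' @param annotations an [annotation_table].
#' @param matrix an [expression_matrix] whose rows define the index space.
#' @param ratio maximum negative:positive row ratio.
#' @param seed integer seed for the negative subsample.
#' @param sentinel gene id marking unmapped rows to exclude.
#' @param min_positives minimum number of positive rows required.
#' @return A `category_task`: list with `term_id`, integer row index vectors
#'   `positives`, `negatives`, `unlabeled`, and `seed`.
#' @export
build_category_task <- function(term_id, annotations, matrix, ratio = 4L,
                                seed = 1L, sentinel = "UNMAPPED",
                                min_positives = 10L) {
  stopifnot(inherits(annotations, "annotation_table"),
            inherits(matrix, "expression_matrix"))
  gene_ids <- matrix$gene_ids
  usable <- which(gene_ids != sentinel)
  annotated_genes <- unique(annotations$gene_id)
  member_genes <- unique(annotations$gene_id[annotations$term_id == term_id])
  positives <- usable[gene_ids[usable] %in% member_genes]
  if (length(positives) < min_positives) {
    stop(sprintf("term %s has %d positive rows, fewer than %d",
                 term_id, length(positives), min_positives))
  }
  pool <- usable[gene_ids[usable] %in% setdiff(annotated_genes, member_genes)]
  if (length(pool) == 0L) stop("empty negative pool for term ", term_id)
  n_neg <- min(ratio * length(positives), length(pool))
  negatives <- with_seed(seed, sort(sample(pool, n_neg)))
  unlabeled <- usable[!(gene_ids[usable] %in% annotated_genes)]
  structure(
    list(term_id = term_id, positives = sort(positives), negatives = negatives,
         unlabeled = sort(unlabeled), seed = as.integer(seed)),
    class = "category_task"
  )
}

#' @export
print.category_task <- function(x, ...) {
  cat(sprintf("category_task %s: %d positives, %d negatives, %d unlabeled\n",
              x$term_id, length(x$positives), length(x$negatives),
              length(x$unlabeled)))
  invisible(x)
}

#' Stratified k-fold partition of a task's labeled rows
#'
#' Splits positives and negatives into `k` folds so that total fold sizes
#' differ by at most one and positive counts per fold differ by at most one
#' (stratification). When sizes do not divide evenly the larger folds come
#' first after a seeded shuffle of fold order, so the assignment is uniform
#' over admissible partitions and reproducible. With
#' `group_duplicates = TRUE`, rows sharing a gene id are forced into the same
#' fold (the default keeps duplicate clones as independent data points, which
#' may land in different folds).
#'
#' @param task a `category_task`.
#' @param k number of folds (the rotation scheme fixes this at 4).
#' @param seed integer seed.
#' @param group_duplicates logical; co-assign duplicate clone rows of a gene.
#' @param gene_ids character vector of gene ids per matrix row; required when
#'   `group_duplicates = TRUE`.
#' @return A `fold_partition`: list with `folds` (list of `k` integer row
#'   index vectors) and `seed`.
#' @export
stratified_partition <- function(task, k = 4L, seed = 1L,
                                 group_duplicates = FALSE, gene_ids = NULL) {
  stopifnot(inherits(task, "category_task"))
  if (length(task$positives) < k) {
    stop("fewer positives than folds: ", length(task$positives), " < ", k)
  }
  pos <- task$positives
  neg <- task$negatives
  n <- length(pos) + length(neg)
  with_seed(seed, {
    fold_order <- sample.int(k)        # larger folds come first in this order
    if (group_duplicates) {
      if (is.null(gene_ids)) stop("gene_ids required when group_duplicates=TRUE")
      pos_units <- split(pos, gene_ids[pos])
      neg_units <- split(neg, gene_ids[neg])
      pos_units <- sample(pos_units)
      neg_units <- sample(neg_units)
    } else {
      pos_units <- as.list(sample(pos))
      neg_units <- as.list(sample(neg))
    }
    folds <- rep(list(integer(0)), k)
    # deal positive units round-robin over the shuffled fold order
    for (i in seq_along(pos_units)) {
      f <- fold_order[(i - 1L) %% k + 1L]
      folds[[f]] <- c(folds[[f]], pos_units[[i]])
    }
    # target total sizes: remainder goes to the first folds in shuffled order
    base <- n %/% k
    target <- rep(base, k)
    r <- n %% k
    if (r > 0L) target[fold_order[seq_len(r)]] <- base + 1L
    # fill with negative units, always topping up the largest deficit
    for (u in neg_units) {
      deficit <- target - lengths(folds)
      f <- which.max(deficit + stats::runif(k, 0, 0.5))  # random tie-break
      folds[[f]] <- c(folds[[f]], u)
    }
  })
  sizes <- lengths(folds)
  if (max(sizes) - min(sizes) > 1L) {
    if (!group_duplicates) stop("internal error: unbalanced partition")
    warning("group_duplicates forced fold sizes differing by more than 1")
  }
  folds <- lapply(folds, sort)
  structure(list(folds = folds, seed = as.integer(seed)),
            class = "fold_partition")
}

#' @export
print.fold_partition <- function(x, ...) {
  cat("fold_partition with sizes:", paste(lengths(x$folds), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a task manifest
#'
#' One row per category task: term id, class sizes, unlabeled count, seed.
#'
#' @param tasks list of `category_task` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_task_manifest <- function(tasks, path) {
  df <- do.call(rbind, lapply(tasks, function(t) {
    data.frame(term_id = t$term_id, n_pos = length(t$positives),
               n_neg = length(t$negatives), n_unlabeled = length(t$unlabeled),
               seed = t$seed, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
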