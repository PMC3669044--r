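#' Precision-recall points for one test fold
#'
#' One point per distinct probability value, with the rule "probability >=
#' threshold => predicted positive", so rows sharing a probability value
#' enter or leave the predicted set together. Precision = true positives /
#' predicted positives; recall = true positives / total positives. As the
#' threshold decreases, recall is non-decreasing and reaches 1 at the lowest
#' threshold; every threshold predicts at least one positive, so precision
#' is always defined.
#'
#' @param probs numeric vector of (averaged) probability estimates for the
#'   fold's labeled rows.
#' @param labels numeric vector in \{-1, +1\}.
#' @return A `pr_curve` data frame: `threshold` (descending distinct
#'   probabilities), `tp`, `pp`, `precision`, `recall`.
#' @export
pr_points <- function(probs, labels) {
  probs <- as.numeric(probs)
  labels <- as.numeric(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("fold contains no positives; precision-recall undefined")
  thresholds <- sort(unique(probs), decreasing = TRUE)
  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]
  pos_sorted <- labels[ord] == 1
  # counts for "probs >= t": cumulative over the sorted values
  idx <- findInterval(-thresholds, -p_sorted)   # last position with p >= t
  cum_tp <- cumsum(pos_sorted)
  tp <- cum_tp[idx]
  pp <- idx
  out <- data.frame(threshold = thresholds, tp = tp, pp = pp,
                    precision = tp / pp, recall = tp / n_pos)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Precision at a fixed recall level
#'
#' Default rule (`"max"`): the maximum precision over thresholds whose recall
#' is at least `r` — the curve's best attainable precision while covering a
#' fraction `r` of the positives. The alternative rule (`"threshold"`)
#' reports the precision at the largest threshold whose recall reaches `r`.
#'
#' @param curve a `pr_curve` from [pr_points()].
#' @param r recall level in (0, 1].
#' @param rule `"max"` (default) or `"threshold"`.
#' @return Precision value in \[0, 1\].
#' @export
precision_at_recall <- function(curve, r, rule = c("max", "threshold")) {
  rule <- match.arg(rule)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
    stop("recall level must lie in (0, 1]")
  }
  ok <- curve$recall >= r
  if (!any(ok)) stop("no threshold attains recall >= ", r)
  if (rule == "max") max(curve$precision[ok])
  else curve$precision[which(ok)[1L]]
}

#' Vertically average fold precision-recall curves
#'
#' Each fold curve is read as precision-as-a-function-of-recall (linear
#' interpolation between points; at a recall attained by several thresholds
#' the best precision is used; constant extrapolation below the curve's
#' smallest recall) and the fold precisions are averaged pointwise on a
#' common recall grid.
#'
#' @param curves list of `pr_curve` objects (>= 2).
#' @param grid numeric recall grid, default 101 points 0, 0.01, ..., 1.
#' @return Data frame `recall`, `precision` (the pointwise mean), plus one
#'   `precision_foldN` column per input curve.
#' @export
vertical_average <- function(curves, grid = seq(0, 1, by = 0.01)) {
  if (length(curves) < 2L) stop("need at least two curves to average")
  if (length(grid) == 0L) stop("empty recall grid")
  per_fold <- vapply(curves, function(cv) {
    rec <- cv$recall
    prec <- cv$precision
    best <- tapply(prec, rec, max)
    r_pts <- as.numeric(names(best))
    p_pts <- as.numeric(best)
    if (length(r_pts) == 1L) return(rep(p_pts, length(grid)))
    stats::approx(r_pts, p_pts, xout = grid, rule = 2L)$y
  }, numeric(length(grid)))
  out <- data.frame(recall = grid, precision = rowMeans(per_fold))
  colnames(per_fold) <- paste0("precision_fold", seq_along(curves))
  cbind(out, per_fold)
}

#' Gene-precision confidence score
#'
#' For an unlabeled gene with fold probability estimate `p_gene`, the score
#' is the maximum precision the fold's classifier can achieve using any
#' threshold less than or equal to `p_gene` — i.e. the best operating point
#' at which this gene would be among the predicted positives. If no curve
#' threshold is <= `p_gene` the gene can never be predicted positive at an
#' admissible operating point and the score is 0. The score is a
#' non-decreasing step function of `p_gene`.
#'
#' @param p_gene probability estimate in (0, 1) (vectorized).
#' @param curve the fold's `pr_curve`.
#' @return Numeric vector of gene-precision scores in \[0, 1\].
#' @export
gene_precision <- function(p_gene, curve) {
  p_gene <- as.numeric(p_gene)
  if (any(p_gene <= 0 | p_gene >= 1)) {
    stop("probability estimates must lie strictly inside (0, 1)")
  }
  # curve thresholds descending; running max of precision from the bottom up
  thr <- curve$threshold
  cummax_from_low <- rev(cummax(rev(curve$precision)))
  vapply(p_gene, function(p) {
    ok <- which(thr <= p)
    if (length(ok) == 0L) 0 else cummax_from_low[ok[1L]]
  }, numeric(1))
}

#' Summarize one category's cross-validated performance
#'
#' Builds the four fold-level precision-recall curves from the labeled rows'
#' averaged probabilities, computes precision at the requested recall levels
#' per fold and their four-fold means, and assigns every unlabeled row a
#' per-fold gene-precision score (from that fold's curve and the row's
#' fold-specific probability) plus its four-fold mean.
#'
#' @param prob_table a `probability_table` from [rotation_cv()].
#' @param recall_levels numeric recall levels, default `c(0.2, 0.3, 0.4)`.
#' @param term_id category identifier carried into the outputs.
#' @param gene_ids optional character vector mapping matrix rows to gene
#'   ids, used to label the outputs.
#' @return List with `performance` (data frame: term_id, one
#'   `prec<level>_fold<f>` column per fold and level, and `prec<level>_mean`
#'   columns), `gene_precision` (data frame: term_id, row, gene_id,
#'   `gp_fold1..4`, `p_fold1..4`, `gp_mean`, `p_mean`), and `curves` (list of
#'   4 `pr_curve`s).
#' @export
summarize_category <- function(prob_table, recall_levels = c(0.2, 0.3, 0.4),
                               term_id = NA_character_, gene_ids = NULL) {
  stopifnot(inherits(prob_table, "probability_table"))
  lab <- prob_table$labeled
  folds_present <- sort(unique(lab$test_fold))
  if (!identical(folds_present, 1:4)) stop("incomplete folds in probability table")
  curves <- lapply(1:4, function(f) {
    sel <- lab$test_fold == f
    pr_points(lab$p_mean[sel], lab$label[sel])
  })
  perf <- data.frame(term_id = term_id)
  for (r in recall_levels) {
    vals <- vapply(curves, precision_at_recall, numeric(1), r = r)
    tag <- paste0("prec", round(100 * r))
    for (f in 1:4) perf[[paste0(tag, "_fold", f)]] <- vals[f]
    perf[[paste0(tag, "_mean")]] <- mean(vals)
  }
  unl <- prob_table$unlabeled
  gp <- data.frame(term_id = rep(term_id, nrow(unl)), row = unl$row)
  gp$gene_id <- if (is.null(gene_ids)) as.character(unl$row) else gene_ids[unl$row]
  for (f in 1:4) {
    p_f <- unl[[paste0("p_fold", f)]]
    gp[[paste0("gp_fold", f)]] <- if (nrow(unl)) gene_precision(p_f, curves[[f]]) else numeric(0)
    gp[[paste0("p_fold", f)]] <- p_f
  }
  gp$gp_mean <- if (nrow(unl)) rowMeans(gp[paste0("gp_fold", 1:4)]) else numeric(0)
  gp$p_mean <- if (nrow(unl)) rowMeans(gp[paste0("p_fold", 1:4)]) else numeric(0)
  list(performance = perf, gene_precision = gp, curves = curves)
}
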