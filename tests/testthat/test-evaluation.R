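test_that("precision-recall points match hand-worked and degenerate cases", {
  cv <- pr_points(c(0.9, 0.8, 0.7, 0.6), c(1, 1, -1, 1))
  at07 <- cv[cv$threshold == 0.7, ]
  expect_equal(at07$precision, 2 / 3)
  expect_equal(at07$recall, 2 / 3)
  expect_equal(cv$recall[nrow(cv)], 1)  # recall ends at 1
  # perfect ranking: precision 1 at every recall
  perfect <- pr_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_true(all(perfect$precision[perfect$threshold >= 0.8] == 1))
  # all scores tied: a single point at prevalence
  tied <- pr_points(rep(0.5, 10), c(rep(1, 2), rep(-1, 8)))
  expect_equal(nrow(tied), 1L)
  expect_equal(tied$precision, 0.2)
  expect_equal(tied$recall, 1)
  expect_error(pr_points(c(0.1, 0.2), c(-1, -1)), "no positives")
})

test_that("pr machinery matches exhaustive enumeration on random instances", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(2:50, 1)
    # duplicated scores exercise the tie rule
    probs <- sample(round(runif(n), sample(c(1, 2, 6), 1)), n, replace = TRUE)
    probs <- pmin(pmax(probs, 1e-4), 1 - 1e-4)
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (!any(labels == 1)) labels[sample(n, 1)] <- 1
    impl <- pr_points(probs, labels)
    ora <- oracle_pr(probs, labels)
    expect_equal(impl$threshold, ora$threshold)
    expect_equal(impl$precision, ora$precision)
    expect_equal(impl$recall, ora$recall)
    r <- sample(c(0.2, 0.3, 0.4, runif(1, 0.01, 1)), 1)
    expect_equal(precision_at_recall(impl, r),
                 oracle_precision_at_recall(probs, labels, r))
    p_gene <- runif(1, 1e-3, 1 - 1e-3)
    expect_equal(gene_precision(p_gene, impl),
                 oracle_gene_precision(p_gene, probs, labels))
  }
})

test_that("precision-at-recall takes the best threshold past the recall bound", {
  # 5 positives in 25; top-2 scores are positives => precision 1 at recall 0.4
  probs <- c(0.99, 0.98, runif(23, 0.05, 0.9))
  labels <- c(1, 1, 1, 1, 1, rep(-1, 20))
  cv <- pr_points(probs, labels)
  expect_equal(precision_at_recall(cv, 0.4), 1.0)
  # the "threshold" rule reports the earliest qualifying point instead
  expect_lte(precision_at_recall(cv, 0.4, rule = "threshold"),
             precision_at_recall(cv, 0.4))
  expect_error(precision_at_recall(cv, 0), "recall level")
  expect_error(precision_at_recall(cv, 1.2), "recall level")
})

test_that("precision-at-recall is non-increasing in r; uniform scores sit at prevalence", {
  set.seed(31)
  probs <- runif(4000)
  labels <- c(rep(1, 800), rep(-1, 3200))
  cv <- pr_points(probs, labels)
  vals <- vapply(seq(0.1, 1, 0.1), function(r) precision_at_recall(cv, r), 0)
  expect_true(all(diff(vals) <= 1e-12))
  expect_lt(abs(precision_at_recall(cv, 0.4) - 0.2), 0.05)
})

test_that("vertical averaging interpolates fold curves on a recall grid", {
  c1 <- data.frame(threshold = c(0.9, 0.5), precision = c(0.8, 0.8),
                   recall = c(0.5, 1))
  c2 <- data.frame(threshold = c(0.9, 0.5), precision = c(0.6, 0.6),
                   recall = c(0.5, 1))
  avg <- vertical_average(list(c1, c2))
  expect_equal(nrow(avg), 101L)
  expect_true(all(abs(avg$precision - 0.7) < 1e-12))
  # identical curves average to themselves
  same <- vertical_average(list(c1, c1))
  expect_true(all(abs(same$precision - 0.8) < 1e-12))
  # averaged precision bounded by the fold extremes at every grid point
  set.seed(7)
  curves <- lapply(1:4, function(i) {
    probs <- runif(40)
    labels <- c(rep(1, 8), rep(-1, 32))
    pr_points(probs, labels)
  })
  avg4 <- vertical_average(curves)
  per_fold <- as.matrix(avg4[, paste0("precision_fold", 1:4)])
  expect_true(all(avg4$precision >= apply(per_fold, 1, min) - 1e-12))
  expect_true(all(avg4$precision <= apply(per_fold, 1, max) + 1e-12))
  expect_error(vertical_average(list(c1)), "two curves")
  expect_error(vertical_average(list(c1, c2), grid = numeric(0)), "empty")
})

test_that("gene precision is the best precision at admissible thresholds", {
  curve <- data.frame(threshold = c(0.9, 0.7, 0.5),
                      precision = c(1.0, 0.8, 0.6),
                      recall = c(0.2, 0.5, 1))
  expect_equal(gene_precision(0.75, curve), 0.8)
  # above every threshold: overall maximum
  expect_equal(gene_precision(0.95, curve), 1.0)
  # below every threshold: never predictable positive => 0
  expect_equal(gene_precision(0.4, curve), 0)
  # non-decreasing step function of the probability
  p_grid <- seq(0.01, 0.99, 0.01)
  expect_true(all(diff(gene_precision(p_grid, curve)) >= 0))
  expect_error(gene_precision(1.2, curve), "inside")
})

test_that("category summaries average the four folds for metrics and genes", {
  ds <- simulate_dataset(study_config(55))
  res <- run_category("GO:S001", ds$annotations, ds$matrix,
                      run_config(seed = 3))
  perf <- res$performance
  for (tag in c("prec20", "prec30", "prec40")) {
    folds <- unlist(perf[paste0(tag, "_fold", 1:4)])
    expect_equal(unname(perf[[paste0(tag, "_mean")]]), mean(folds))
    expect_true(all(folds >= 0 & folds <= 1))
  }
  gp <- res$gene_precision
  expect_equal(gp$gp_mean, rowMeans(gp[, paste0("gp_fold", 1:4)]))
  # within each fold, gene precision is monotone in the probability estimate
  for (f in 1:4) {
    ord <- order(gp[[paste0("p_fold", f)]])
    expect_true(all(diff(gp[[paste0("gp_fold", f)]][ord]) >= -1e-12))
  }
  expect_error(summarize_category(structure(list(
    labeled = data.frame(test_fold = c(1, 2, 3), label = c(1, 1, -1),
                         p_mean = c(0.5, 0.4, 0.3), row = 1:3),
    unlabeled = data.frame(row = integer(0))), class = "probability_table")),
    "incomplete")
})

test_that("permuted labels pull mean precision-at-40 to the prevalence baseline", {
  set.seed(99)
  vals <- replicate(200, {
    probs <- runif(100)
    labels <- sample(c(rep(1, 20), rep(-1, 80)))
    precision_at_recall(pr_points(probs, labels), 0.4)
  })
  expect_lt(abs(mean(vals) - 0.2), 0.1)
})
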