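# small helper: an expression matrix with one row per gene id
rows_for <- function(gene_ids) {
  n <- length(gene_ids)
  expression_matrix(matrix(rnorm(n * 3), n, 3), sprintf("CL%03d", 1:n),
                    gene_ids, c("c1", "c2", "c3"))
}

test_that("category selection enforces the inclusive 10-999 size window", {
  genes <- sprintf("G%04d", 1:1200)
  ann <- annotation_table(
    gene_id = c(genes[1:9], genes[1:10], genes[1:1000], genes[1:20]),
    term_id = rep(c("GO:small", "GO:edge10", "GO:big", "GO:ok"),
                  c(9, 10, 1000, 20)))
  sel <- select_categories(ann, genes)
  expect_setequal(sel$term_id, c("GO:edge10", "GO:ok"))
  expect_equal(sel$n_members[sel$term_id == "GO:edge10"], 10L)
  # counts are over represented genes only
  sel2 <- select_categories(ann, genes[1:15])
  expect_equal(sel2$n_members[sel2$term_id == "GO:ok"], 15L)
  # a 1000th member re-enters when the window is widened
  expect_true("GO:big" %in% select_categories(ann, genes, max_size = 1000)$term_id)
  expect_error(select_categories(ann, genes, min_size = 5, max_size = 4), "min_size")
})

test_that("negative sampling draws 1:4 from annotated non-members only", {
  set.seed(42)
  genes <- sprintf("G%04d", 1:600)
  mat <- rows_for(genes)
  # 20 positives, 500 annotated others, 80 un-annotated
  ann <- annotation_table(
    gene_id = c(genes[1:20], genes[21:520]),
    term_id = rep(c("GO:T", "GO:other"), c(20, 500)))
  task <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 7)
  expect_equal(length(task$positives), 20L)
  expect_equal(length(task$negatives), 80L)
  expect_equal(length(task$unlabeled), 80L)
  expect_length(intersect(task$positives, task$negatives), 0L)
  # un-annotated genes never sampled as negatives
  expect_length(intersect(task$negatives, task$unlabeled), 0L)
  expect_true(all(mat$gene_ids[task$negatives] %in% genes[21:520]))
  # determinism and seed sensitivity
  task2 <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 7)
  expect_identical(task2$negatives, task$negatives)
  task3 <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 8)
  expect_false(identical(task3$negatives, task$negatives))
})

test_that("scarce negative pools are taken whole and empty pools error", {
  set.seed(1)
  genes <- sprintf("G%03d", 1:90)
  mat <- rows_for(genes)
  ann <- annotation_table(gene_id = c(genes[1:20], genes[21:70]),
                          term_id = rep(c("GO:T", "GO:other"), c(20, 50)))
  task <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 1)
  expect_equal(length(task$negatives), 50L)
  only_pos <- annotation_table(genes[1:20], rep("GO:T", 20))
  expect_error(build_category_task("GO:T", only_pos, mat, seed = 1),
               "empty negative pool")
  expect_error(build_category_task("GO:T", ann, mat, seed = 1, min_positives = 21),
               "fewer than")
})

test_that("stratified partition balances totals and positives", {
  set.seed(3)
  genes <- sprintf("G%04d", 1:500)
  mat <- rows_for(genes)
  ann <- annotation_table(gene_id = c(genes[1:20], genes[21:420]),
                          term_id = rep(c("GO:T", "GO:other"), c(20, 400)))
  task <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 2)
  part <- stratified_partition(task, seed = 5)
  expect_equal(sort(unlist(part$folds)), sort(c(task$positives, task$negatives)))
  expect_equal(lengths(part$folds), rep(25L, 4))
  pos_counts <- vapply(part$folds, function(f) sum(f %in% task$positives), 0L)
  expect_equal(pos_counts, rep(5L, 4))
  expect_identical(stratified_partition(task, seed = 5)$folds, part$folds)
})

test_that("uneven sizes split as evenly as admissible (21 pos + 81 neg)", {
  set.seed(4)
  genes <- sprintf("G%04d", 1:500)
  mat <- rows_for(genes)
  ann <- annotation_table(gene_id = c(genes[1:21], genes[22:421]),
                          term_id = rep(c("GO:T", "GO:other"), c(21, 400)))
  task <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 2)
  # trim negatives to 81 to hit the 21+81 case exactly
  task$negatives <- task$negatives[1:81]
  part <- stratified_partition(task, seed = 11)
  expect_equal(sort(lengths(part$folds)), c(25L, 25L, 26L, 26L))
  pos_counts <- vapply(part$folds, function(f) sum(f %in% task$positives), 0L)
  expect_equal(sort(pos_counts), c(5L, 5L, 5L, 6L))
})

test_that("stratification property holds across many seeds", {
  set.seed(9)
  genes <- sprintf("G%04d", 1:400)
  mat <- rows_for(genes)
  ann <- annotation_table(gene_id = c(genes[1:23], genes[24:350]),
                          term_id = rep(c("GO:T", "GO:other"), c(23, 327)))
  task <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 2)
  for (s in 1:300) {
    part <- stratified_partition(task, seed = s)
    sizes <- lengths(part$folds)
    pos_counts <- vapply(part$folds, function(f) sum(f %in% task$positives), 0L)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_lte(max(pos_counts) - min(pos_counts), 1L)
    expect_equal(sum(sizes), length(task$positives) + length(task$negatives))
  }
  expect_error(stratified_partition(task, k = 24L, seed = 1), "fewer positives")
})

test_that("duplicate clone rows can be forced into one fold", {
  set.seed(12)
  gene_ids <- rep(sprintf("G%03d", 1:60), each = 2)  # every gene duplicated
  n <- length(gene_ids)
  mat <- expression_matrix(matrix(rnorm(n * 3), n, 3), sprintf("CL%03d", 1:n),
                           gene_ids, c("c1", "c2", "c3"))
  ann <- annotation_table(gene_id = c(sprintf("G%03d", 1:12), sprintf("G%03d", 13:60)),
                          term_id = rep(c("GO:T", "GO:other"), c(12, 48)))
  task <- build_category_task("GO:T", ann, mat, ratio = 4, seed = 3)
  part <- stratified_partition(task, seed = 6, group_duplicates = TRUE,
                               gene_ids = mat$gene_ids)
  fold_of <- integer(0)
  for (f in 1:4) fold_of[part$folds[[f]]] <- f
  labeled <- c(task$positives, task$negatives)
  by_gene <- split(fold_of[labeled], mat$gene_ids[labeled])
  expect_true(all(vapply(by_gene, function(v) length(unique(v)) == 1L, TRUE)))
})
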