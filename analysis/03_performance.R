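#!/usr/bin/env Rscript
# Evaluate the cross-validated runs against the planted truth: fold-averaged
# precision-recall curves per category (vertical averaging) and recovery of
# the hidden category members. Writes tables under results/tables/.

suppressPackageStartupMessages(library(coexpGO))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
outdir <- "results/tables"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

mat <- load_expression_matrix("results/data/expression.tsv")
ann <- load_annotations("results/data/annotations.tsv", format = "two_column")
truth <- read.delim("results/data/truth.tsv", colClasses = c(
  term_id = "character", gene_id = "character", hidden = "logical"))
cfg <- run_config(seed = seed)

# vertically averaged PR curves for the planted categories
planted <- intersect(unique(truth$term_id),
                     select_categories(ann, unique(mat$gene_ids))$term_id)
avg_curves <- list()
hidden_summary <- list()
for (term in planted) {
  res <- run_category(term, ann, mat, cfg)
  avg <- vertical_average(res$curves)
  avg$term_id <- term
  avg_curves[[term]] <- avg[, c("term_id", "recall", "precision")]
  hid <- truth$gene_id[truth$term_id == term & truth$hidden]
  gp <- res$gene_precision
  sel <- gp$gene_id %in% hid
  scores <- if (any(sel)) tapply(gp$gp_mean[sel], gp$gene_id[sel], mean) else numeric(0)
  hidden_summary[[term]] <- data.frame(
    term_id = term, n_hidden = length(hid),
    mean_gene_precision = if (length(scores)) mean(scores) else NA_real_,
    recovered_at_0.75 = sum(scores >= 0.75))
  cat(sprintf("%s: prec-at-40 mean %.3f; hidden members %d, recovered %d\n",
              term, res$performance$prec40_mean, length(hid),
              sum(scores >= 0.75)))
}
write.table(do.call(rbind, avg_curves), file.path(outdir, "pr_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, hidden_summary),
            file.path(outdir, "hidden_member_recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/tables/pr_curves.tsv and hidden_member_recovery.tsv\n")
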