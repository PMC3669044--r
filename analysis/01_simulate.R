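#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a desk-scale time-course expression
# matrix with planted co-expressed GO-BP-style categories, hidden members
# among the un-annotated pool, duplicate clone rows and missing cells.
# Writes TSVs under results/data/ for the downstream steps.

suppressPackageStartupMessages(library(coexpGO))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(
  n_genes = 400L, n_conditions = 60L,
  categories = list(
    list(term_id = "GO:S001", n_annotated = 30L, n_hidden = 10L),
    list(term_id = "GO:S002", n_annotated = 20L, n_hidden = 6L),
    list(term_id = "GO:W001", n_annotated = 25L, n_hidden = 8L, signal = 1),
    list(term_id = "GO:N001", n_annotated = 30L, n_hidden = 0L, signal = 0)),
  signal = 2, noise_sd = 0.5, missing_frac = 0.05,
  frac_unannotated = 0.35, dup_clone_frac = 0.1, seed = seed)
ds <- simulate_dataset(cfg)

write_expression_matrix(ds$matrix, file.path(outdir, "expression.tsv"))
writeLines(paste(ds$annotations$gene_id, ds$annotations$term_id, sep = "\t"),
           file.path(outdir, "annotations.tsv"))
truth <- do.call(rbind, lapply(names(ds$truth), function(term) {
  data.frame(term_id = term, gene_id = ds$truth[[term]],
             hidden = ds$truth[[term]] %in% ds$hidden[[term]])
}))
write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d clone rows x %d conditions (%d genes, seed %d)\n",
            nrow(ds$matrix$values), ncol(ds$matrix$values),
            length(unique(ds$matrix$gene_ids)), seed))
cat(sprintf("planted categories: %s\n", paste(names(ds$truth), collapse = ", ")))
cat(sprintf("un-annotated genes: %d (%d of them hidden category members)\n",
            length(setdiff(unique(ds$matrix$gene_ids), ds$annotations$gene_id)),
            sum(lengths(ds$hidden))))
cat("wrote", file.path(outdir, c("expression.tsv", "annotations.tsv", "truth.tsv")),
    sep = "\n  ")
cat("\n")
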