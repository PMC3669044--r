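#!/usr/bin/env Rscript
# Final report: high-precision categories, gene-function predictions and
# coverage arithmetic from the pipeline run, plus the FISH concordance
# tallies for the two published category tables shipped with the package.
# Writes results/report/.

suppressPackageStartupMessages(library(coexpGO))

outdir <- "results/report"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

summ <- jsonlite::read_json("results/run/summary.json")
perf <- read.delim("results/run/performance.tsv")
high <- select_high_precision_categories(perf)
pred <- read.delim("results/run/predictions.tsv")

cat(sprintf("high-precision categories (mean prec-at-40 >= 0.75): %d\n",
            nrow(high)))
if (nrow(high)) print(high[, c("term_id", "prec40_mean")], row.names = FALSE,
                      digits = 3)
cat(sprintf("predictions: %d pairs for %d genes\n", nrow(pred),
            length(unique(pred$gene_id))))
cat(sprintf("un-annotated on array: %d%%; of those, predicted: %s%%\n",
            summ$coverage$unannotated$percent,
            if (is.null(summ$coverage$predicted)) "NA"
            else summ$coverage$predicted$percent))

# concordance arithmetic for the two published FISH validation tables
for (f in c(dna_replication = "fish_dna_replication.tsv",
            oxidative_phosphorylation = "fish_oxidative_phosphorylation.tsv")) {
  tbl <- load_concordance_table(system.file("extdata", f, package = "coexpGO"))
  cc <- fish_concordance_summary(tbl)
  cat(sprintf("FISH concordance (%s): %d/%d = %d%%\n",
              sub("fish_(.*)\\.tsv", "\\1", f), cc$n_plus, cc$n_marked,
              cc$percent))
}

write.table(high, file.path(outdir, "high_precision_categories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pred, file.path(outdir, "predictions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/report/\n")
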