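# coexpGO

Calibrated, confidence-scored prediction of Gene Ontology Biological
Process (GO-BP) annotations from gene-expression profiles.

A large fraction of genes in well-studied genomes still lack any GO-BP
term, while expression compendia — developmental time courses in
particular — capture the co-expression that genes acting in one process tend
to share. coexpGO is for computational biologists who want to turn such a
compendium (rows = cDNA clones/genes, columns = conditions) plus an existing
GO-BP annotation table into ranked, per-gene confidence-scored annotation
proposals for the un-annotated genes, with honest cross-validated precision
estimates per category.

## Method

For every GO-BP category with between 10 and 999 represented member genes,
the package trains an independent two-class SVM:

- **Kernel:** radial basis,
  `K(x, y) = exp(-||x - y||² / σ²)`, with `σ` set to the median distance
  from positive training points to their nearest negative training point.
- **Imbalance control:** negatives are a 1:4 subsample of annotated
  non-members, and each training point's kernel diagonal is augmented by
  `λ·|C|/N` (`λ = m/2`, `m` = median kernel diagonal), a 2-norm soft margin
  that regularizes the majority class harder. The dual
  `min ½αᵀQα − Σαᵢ` s.t. `Σαᵢyᵢ = 0, αᵢ ≥ 0` is solved by an SMO-type
  solver on the precomputed kernel.
- **Calibration:** discriminants are mapped to posterior probabilities
  `p(y=1|x) = 1/(1 + exp(a·f(x) + b))`, fitted on a held-out fold with
  smoothed targets `(N₊+1)/(N₊+2)` and `1/(N₋+2)` so perfect separation
  stays well posed.
- **Rotation (double cross-validation):** a stratified 4-fold split; for
  each test fold the other three folds rotate through the calibration role
  (12 SVM fits per category); each gene's three probability estimates are
  averaged.
- **Scores:** per-fold precision-recall curves give each category its mean
  *precision at recall 0.4* (maximum precision at recall ≥ 0.4, averaged
  over folds), and each un-annotated gene a *gene precision* score — the
  best precision attainable at any threshold at or below the gene's
  probability, averaged over folds. Categories at mean precision-at-40
  ≥ 0.75 and gene-category pairs at gene precision ≥ 0.75 (both inclusive)
  are reported.

A synthetic time-course generator (`simulate_dataset()`) plants
co-expressed categories with hidden members so the whole pipeline is
testable without any external download. See the vignette
(`vignettes/gene-function-prediction.Rmd`) for the full model description,
parameter meanings, and design rationale.

## Worked example

```r
library(coexpGO)

cfg <- simulation_config(
  n_genes = 300, n_conditions = 60,
  categories = list(
    list(term_id = "GO:S001", n_annotated = 30, n_hidden = 10),
    list(term_id = "GO:N001", n_annotated = 30, n_hidden = 0, signal = 0)),
  seed = 7)
ds <- simulate_dataset(cfg)
#> synthetic_dataset: 330 rows x 60 conditions, 2 planted categories, 195 annotation pairs

res <- run_pipeline(ds$matrix, ds$annotations, run_config(seed = 7),
                    terms = c("GO:S001", "GO:N001"))
#> pipeline_result: 2 categories run (0 skipped), 1 high-precision, 16 predictions

res$performance[, c("term_id", "prec20_mean", "prec30_mean", "prec40_mean")]
#>  term_id prec20_mean prec30_mean prec40_mean
#>  GO:N001       0.231       0.231       0.231
#>  GO:S001       1.000       1.000       1.000

head(res$predictions[, c("term_id", "gene_id", "gp_mean")], 5)
#>   term_id gene_id gp_mean
#> 1 GO:S001   G0031       1
#> 2 GO:S001   G0033       1
#> 3 GO:S001   G0035       1
#> 4 GO:S001   G0036       1
#> 5 GO:S001   G0037       1
```

The strong planted category (`GO:S001`, signal-to-noise 4) is recovered at
precision 1.0 across all recall levels and qualifies as high-precision; the
null category (`GO:N001`, no signal) sits near the 0.2 prevalence baseline
of 1:4 sampling and is rejected. All 10 hidden members of the strong
category appear among the emitted predictions with gene precision ≥ 0.75 —
the generator kept them out of the annotation table, so the pipeline found
them from co-expression alone.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and leave their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1      # planted dataset -> results/data/
Rscript analysis/02_run_pipeline.R --seed 1  # rotation CV     -> results/run/
Rscript analysis/03_performance.R --seed 1   # PR curves, hidden-member recovery
Rscript analysis/04_report.R                 # selections, coverage, FISH tallies
```

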