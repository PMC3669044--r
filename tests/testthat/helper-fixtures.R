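# Shared fixture builders: tiny on-disk files and the standard synthetic
# study configuration used by the pipeline-level tests.

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# 3 clones x 4 conditions, one duplicate gene pair, one missing cell
tiny_matrix_file <- function() {
  write_tsv_lines(c(
    "clone_id\tgene_id\tc1\tc2\tc3\tc4",
    "CL1\tGA\t1.5\t-0.25\t0\t2",
    "CL2\tGA\t0.5\tNA\t1\t-1",
    "CL3\tGB\t-2\t0.125\t3\t0.75"))
}

# standard synthetic study: one strong planted category (30 annotated + 10
# hidden members, signal/noise = 4 over 60 conditions) and one null category
# of the same size, inside 300 genes
study_config <- function(seed, null_signal = 0) {
  simulation_config(
    n_genes = 300L, n_conditions = 60L,
    categories = list(
      list(term_id = "GO:S001", n_annotated = 30L, n_hidden = 10L),
      list(term_id = "GO:N001", n_annotated = 30L, n_hidden = 0L,
           signal = null_signal)),
    signal = 2, noise_sd = 0.5, missing_frac = 0.05,
    frac_unannotated = 0.35, dup_clone_frac = 0.1, seed = seed)
}
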