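#' Configuration for the synthetic time-course generator
#'
#' Describes a desk-scale dataset with the statistical structure the analysis
#' assumes: genes-by-conditions log-ratio matrix, planted co-expressed
#' categories whose members share a smooth latent temporal profile plus
#' independent noise, a pool of un-annotated genes some of which secretly
#' belong to planted categories (hidden members, ground truth retained), a
#' configurable fraction of missing cells, and duplicate clone rows.
#'
#' @param n_genes total number of genes.
#' @param n_conditions number of array conditions (time points).
#' @param categories list of lists, each with `term_id`,
#'   `n_annotated` (members carrying the annotation), `n_hidden` (members
#'   generated from the same profile but left un-annotated), and optional
#'   `signal` overriding the global amplitude for that category.
#' @param signal within-category profile amplitude, in log-ratio units.
#' @param noise_sd per-cell Gaussian noise standard deviation.
#' @param missing_frac fraction of cells masked as missing, in \[0, 1).
#' @param frac_unannotated target fraction of genes with no GO-BP
#'   annotation (hidden members count towards it).
#' @param dup_clone_frac fraction of genes given a second, re-noised clone
#'   row.
#' @param bg_category_size size of the filler categories that annotate
#'   background genes.
#' @param seed integer master seed for the generator.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 400L, n_conditions = 60L,
                              categories = list(
                                list(term_id = "GO:S001", n_annotated = 30L,
                                     n_hidden = 10L)),
                              signal = 2, noise_sd = 0.5,
                              missing_frac = 0.05, frac_unannotated = 0.35,
                              dup_clone_frac = 0.1, bg_category_size = 50L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_conditions = as.integer(n_conditions),
              categories = categories, signal = signal, noise_sd = noise_sd,
              missing_frac = missing_frac,
              frac_unannotated = frac_unannotated,
              dup_clone_frac = dup_clone_frac,
              bg_category_size = as.integer(bg_category_size),
              seed = as.integer(seed))
  if (cfg$signal < 0 || cfg$noise_sd < 0) stop("signal and noise_sd must be >= 0")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    stop("missing_frac must lie in [0, 1)")
  }
  n_members <- sum(vapply(cfg$categories, function(ct) {
    ct$n_annotated + (ct$n_hidden %||% 0L)
  }, numeric(1)))
  if (n_members > cfg$n_genes) stop("category members exceed n_genes")
  structure(cfg, class = "simulation_config")
}

# smooth latent profile over the condition axis: low-order trigonometric
# shape, standardized to mean 0 / sd 1 so `signal` sets the amplitude scale
latent_profile <- function(n_conditions) {
  tt <- seq(0, 1, length.out = n_conditions)
  y <- numeric(n_conditions)
  for (h in 1:3) {
    y <- y + stats::rnorm(1, 0, 1 / h) * sin(2 * pi * h * tt) +
      stats::rnorm(1, 0, 1 / h) * cos(2 * pi * h * tt)
  }
  (y - mean(y)) / stats::sd(y)
}

#' Simulate a synthetic time-course dataset with planted categories
#'
#' Each planted category draws one smooth latent profile; member rows are
#' `amplitude * profile + noise` with per-gene amplitude jittered by +/-20%
#' so members are correlated but not identical; background rows are pure
#' noise. Hidden category members are generated from the same process as
#' annotated members but omitted from the annotation table (they appear
#' un-annotated; the truth map keeps them for evaluation). Background genes
#' are split between an annotated pool (assigned filler terms so they can
#' serve as negatives) and an un-annotated pool sized to the configured
#' fraction. A `dup_clone_frac` fraction of genes gets a second clone row
#' with fresh noise, and `missing_frac` of cells are masked uniformly at
#' random. All randomness derives from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A `synthetic_dataset`: list with `matrix` (an
#'   [expression_matrix]), `annotations` (an [annotation_table], hidden
#'   members omitted), `truth` (named list term -> full member gene ids,
#'   hidden included), `hidden` (named list term -> hidden member gene ids),
#'   and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(n))
    condition_ids <- sprintf("T%03d", seq_len(cfg$n_conditions))
    signal_row <- matrix(0, n, cfg$n_conditions)
    truth <- list()
    hidden <- list()
    ann_gene <- character(0)
    ann_term <- character(0)
    next_gene <- 1L
    for (ct in cfg$categories) {
      n_ann <- ct$n_annotated
      n_hid <- ct$n_hidden %||% 0L
      amp <- ct$signal %||% cfg$signal
      members <- next_gene:(next_gene + n_ann + n_hid - 1L)
      next_gene <- next_gene + n_ann + n_hid
      profile <- latent_profile(cfg$n_conditions)
      for (g in members) {
        jitter <- stats::runif(1, 0.8, 1.2)
        signal_row[g, ] <- amp * jitter * profile
      }
      ann_members <- members[seq_len(n_ann)]
      hid_members <- if (n_hid > 0L) members[(n_ann + 1L):(n_ann + n_hid)] else integer(0)
      truth[[ct$term_id]] <- gene_ids[members]
      hidden[[ct$term_id]] <- gene_ids[hid_members]
      ann_gene <- c(ann_gene, gene_ids[ann_members])
      ann_term <- c(ann_term, rep(ct$term_id, n_ann))
    }
    # background genes: annotate enough of them (filler terms) that the
    # un-annotated fraction comes out at frac_unannotated
    background <- if (next_gene <= n) next_gene:n else integer(0)
    n_unann_target <- round(cfg$frac_unannotated * n)
    n_hidden_total <- sum(lengths(hidden))
    n_unann_bg <- max(0L, min(length(background),
                              n_unann_target - n_hidden_total))
    bg_shuffled <- if (length(background)) sample(background) else integer(0)
    bg_unann <- utils::head(bg_shuffled, n_unann_bg)
    bg_ann <- setdiff(bg_shuffled, bg_unann)
    if (length(bg_ann)) {
      n_bg_terms <- ceiling(length(bg_ann) / cfg$bg_category_size)
      bg_terms <- sprintf("GO:BG%02d", seq_len(n_bg_terms))
      assignment <- rep(bg_terms, each = cfg$bg_category_size)[seq_along(bg_ann)]
      ann_gene <- c(ann_gene, gene_ids[bg_ann])
      ann_term <- c(ann_term, assignment)
    }
    # clone rows: one per gene, plus re-noised duplicates for a fraction
    n_dup <- round(cfg$dup_clone_frac * n)
    dup_genes <- if (n_dup > 0L) sort(sample.int(n, n_dup)) else integer(0)
    row_gene <- c(seq_len(n), dup_genes)
    row_ids <- sprintf("CL%05d", seq_along(row_gene))
    values <- signal_row[row_gene, , drop = FALSE] +
      matrix(stats::rnorm(length(row_gene) * cfg$n_conditions, 0, cfg$noise_sd),
             length(row_gene), cfg$n_conditions)
    mask <- matrix(stats::runif(length(values)) < cfg$missing_frac,
                   nrow(values), ncol(values))
    values[mask] <- NA_real_
    mat <- expression_matrix(values, row_ids, gene_ids[row_gene],
                             condition_ids, mask)
    structure(
      list(matrix = mat,
           annotations = annotation_table(ann_gene, ann_term),
           truth = truth, hidden = hidden, config = cfg),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d rows x %d conditions, %d planted categories, %d annotation pairs\n",
    nrow(x$matrix$values), ncol(x$matrix$values), length(x$truth),
    nrow(x$annotations)))
  invisible(x)
}

#' Simulate discriminant values with known sigmoid parameters
#'
#' Test harness for the calibration fit: draws `f` from a standard normal
#' and labels from `P(y = +1 | f) = 1 / (1 + exp(a * f + b))`, the same
#' sigmoid family the calibration module fits.
#'
#' @param a,b sigmoid parameters (note: negative `a` means larger `f` favors
#'   the positive class).
#' @param n number of points (>= 10).
#' @param seed integer seed.
#' @return List with `f` (numeric) and `labels` (in \{-1, +1\}).
#' @export
simulate_discriminants <- function(a, b, n, seed = 1L) {
  if (n < 10L) stop("n must be at least 10")
  with_seed(seed, {
    f <- stats::rnorm(n)
    p <- 1 / (1 + exp(a * f + b))
    labels <- ifelse(stats::runif(n) < p, 1, -1)
    list(f = f, labels = labels)
  })
}
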