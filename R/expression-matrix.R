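#' Expression matrix container
#'
#' An `expression_matrix` holds a clones/genes-by-conditions matrix of
#' normalized log-ratio values together with a missingness mask. Rows are
#' cDNA clones; several rows may map to the same gene (duplicate clones are
#' deliberately retained as separate data points). Each row is one feature
#' vector for classification, with dimensionality equal to the number of
#' array conditions.
#'
#' @param values numeric matrix, rows = clones, columns = conditions.
#' @param row_ids character vector of unique clone identifiers.
#' @param gene_ids character vector of gene identifiers, one per row;
#'   duplicates allowed.
#' @param condition_ids character vector of condition labels.
#' @param missing_mask logical matrix of the same shape as `values`; `TRUE`
#'   marks a missing cell. Defaults to `is.na(values)`.
#'
#' @return An object of class `expression_matrix`: a list with fields
#'   `values`, `row_ids`, `gene_ids`, `condition_ids`, `missing_mask`.
#' @export
expression_matrix <- function(values, row_ids, gene_ids, condition_ids,
                              missing_mask = is.na(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  missing_mask <- as.matrix(missing_mask)
  if (!is.logical(missing_mask)) stop("missing_mask must be logical")
  if (!all(dim(values) == dim(missing_mask))) {
    stop("values and missing_mask must have the same shape")
  }
  row_ids <- as.character(row_ids)
  gene_ids <- as.character(gene_ids)
  condition_ids <- as.character(condition_ids)
  if (length(row_ids) != nrow(values)) stop("row_ids length != number of rows")
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != number of rows")
  if (length(condition_ids) != ncol(values)) {
    stop("condition_ids length != number of columns")
  }
  if (anyDuplicated(row_ids)) stop("row_ids must be unique")
  if (ncol(values) < 1L) stop("at least one condition required")
  if (any(!is.finite(values[!missing_mask]))) {
    stop("non-finite value in a cell not flagged as missing")
  }
  dimnames(values) <- list(row_ids, condition_ids)
  dimnames(missing_mask) <- list(row_ids, condition_ids)
  structure(
    list(values = values, row_ids = row_ids, gene_ids = gene_ids,
         condition_ids = condition_ids, missing_mask = missing_mask),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d rows (%d genes) x %d conditions, %d missing cells\n",
    nrow(x$values), length(unique(x$gene_ids)), ncol(x$values),
    sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' Expected layout: first row is the condition header, first column the clone
#' identifier, and (optionally) the second column a gene identifier. Cells
#' equal to one of the NA tokens (default `"NA"` or empty) are flagged in the
#' missing mask; any other non-numeric cell is a parse error naming the
#' offending line.
#'
#' @param path path to a TSV file.
#' @param gene_id_column logical; is the second column a gene id? If `FALSE`,
#'   gene ids are taken equal to clone ids.
#' @param na_tokens character vector of cell values to treat as missing.
#' @return An [expression_matrix].
#' @export
load_expression_matrix <- function(path, gene_id_column = TRUE,
                                   na_tokens = c("NA", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("malformed file: need a header and >= 1 data line")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_meta <- if (gene_id_column) 2L else 1L
  # the header may or may not carry labels for the id column(s); disambiguate
  # against the width of the first data line
  n_data <- length(fields[[2L]])
  if (length(header) == n_data) {
    condition_ids <- header[-seq_len(n_meta)]
  } else if (length(header) == n_data - n_meta) {
    condition_ids <- header
  } else {
    stop(sprintf(
      "malformed header on line 1: %d columns against %d in the first data line",
      length(header), n_data))
  }
  n_cond <- length(condition_ids)
  if (n_cond < 1L) stop("malformed header on line 1: no condition columns")
  n_row <- length(fields) - 1L
  values <- matrix(NA_real_, n_row, n_cond)
  missing <- matrix(FALSE, n_row, n_cond)
  row_ids <- character(n_row)
  gene_ids <- character(n_row)
  for (i in seq_len(n_row)) {
    f <- fields[[i + 1L]]
    if (length(f) != n_meta + n_cond) {
      stop(sprintf("parse error on line %d: expected %d columns, found %d",
                   i + 1L, n_meta + n_cond, length(f)))
    }
    row_ids[i] <- f[1L]
    gene_ids[i] <- if (gene_id_column) f[2L] else f[1L]
    cells <- f[(n_meta + 1L):(n_meta + n_cond)]
    is_na <- cells %in% na_tokens
    num <- suppressWarnings(as.numeric(cells))
    bad <- !is_na & is.na(num)
    if (any(bad)) {
      stop(sprintf("parse error on line %d: non-numeric cell '%s'",
                   i + 1L, cells[which(bad)[1L]]))
    }
    values[i, !is_na] <- num[!is_na]
    missing[i, ] <- is_na
  }
  expression_matrix(values, row_ids, gene_ids, condition_ids, missing)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression_matrix()]: finite cells round-trip
#' bit-identically (full precision via `format(..., digits = 17)`), missing
#' cells are written as the NA token.
#'
#' @param x an [expression_matrix].
#' @param path output path.
#' @param na_token string written for missing cells.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, na_token = "NA") {
  stopifnot(inherits(x, "expression_matrix"))
  cells <- matrix("", nrow(x$values), ncol(x$values))
  cells[!x$missing_mask] <-
    format(x$values[!x$missing_mask], digits = 17, trim = TRUE,
           scientific = FALSE)
  cells[x$missing_mask] <- na_token
  header <- paste(c("clone_id", "gene_id", x$condition_ids), collapse = "\t")
  body <- vapply(seq_len(nrow(cells)), function(i) {
    paste(c(x$row_ids[i], x$gene_ids[i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GO Biological Process annotation table
#'
#' Two input dialects: `"two_column"` (gene id, tab, term id) and `"gaf"`
#' (GO Annotation File 2.x; column 2 = object id, column 5 = GO id, column 9
#' = aspect). For GAF input only Biological Process rows (aspect `"P"`) are
#' kept; rows with an unknown aspect code are skipped with a warning.
#' Duplicate (gene, term) pairs collapse to one (set semantics), so loading a
#' file concatenated with itself gives the same table.
#'
#' @param path path to the annotation file.
#' @param format `"two_column"` or `"gaf"`.
#' @return An `annotation_table`: data frame with character columns
#'   `gene_id`, `term_id`, one row per distinct pair, plus attribute
#'   `aspect = "P"`.
#' @export
load_annotations <- function(path, format = c("two_column", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) {
    return(annotation_table(character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "two_column") {
    ok <- lengths(fields) >= 2L
    if (!all(ok)) stop("malformed two-column annotation line: ", which(!ok)[1L])
    gene <- vapply(fields, `[[`, "", 1L)
    term <- vapply(fields, `[[`, "", 2L)
  } else {
    ok <- lengths(fields) >= 9L
    if (!all(ok)) stop("malformed GAF line: ", which(!ok)[1L])
    aspect <- vapply(fields, `[[`, "", 9L)
    unknown <- !(aspect %in% c("P", "F", "C"))
    if (any(unknown)) {
      warning(sum(unknown), " GAF row(s) with unknown aspect code skipped")
    }
    keep <- aspect == "P"
    gene <- vapply(fields[keep], `[[`, "", 2L)
    term <- vapply(fields[keep], `[[`, "", 5L)
  }
  annotation_table(gene, term)
}

#' Construct an annotation table from gene/term vectors
#'
#' @param gene_id,term_id character vectors of equal length.
#' @return Deduplicated `annotation_table` data frame (columns `gene_id`,
#'   `term_id`), Biological Process aspect.
#' @export
annotation_table <- function(gene_id, term_id) {
  gene_id <- as.character(gene_id)
  term_id <- as.character(term_id)
  stopifnot(length(gene_id) == length(term_id))
  if (any(!nzchar(term_id))) stop("empty term_id in annotation table")
  if (any(!nzchar(gene_id))) stop("empty gene_id in annotation table")
  df <- unique(data.frame(gene_id = gene_id, term_id = term_id,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "aspect") <- "P"
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read a clone-to-gene identifier map
#'
#' Two-column TSV: clone id, tab, primary gene id (FBgn-style).
#'
#' @param path path to the map file.
#' @return Named character vector: `map[clone_id] == gene_id`.
#' @export
load_id_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("id map must have two columns")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Map clone identifiers to primary gene identifiers
#'
#' Replaces each row's gene id by `map[row_id]`. Rows whose clone is absent
#' from the map are retained (so row counts stay auditable) with the sentinel
#' gene id and reported via a warning; they are excluded later at
#' task-building time.
#'
#' @param x an [expression_matrix].
#' @param map named character vector (clone id -> gene id).
#' @param sentinel gene id assigned to unmapped rows.
#' @return The re-identified [expression_matrix].
#' @export
map_ids <- function(x, map, sentinel = "UNMAPPED") {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(map) == 0L) stop("empty id map")
  mapped <- unname(map[x$row_ids])
  miss <- is.na(mapped)
  if (any(miss)) {
    warning(sum(miss), " clone(s) absent from id map kept with sentinel id: ",
            paste(utils::head(x$row_ids[miss], 5L), collapse = ", "))
    mapped[miss] <- sentinel
  }
  x$gene_ids <- mapped
  x
}

#' Impute missing expression values
#'
#' `"zero"` sets missing cells to 0 (no change on the log-ratio scale);
#' `"row_mean"` uses the row's observed mean and errors on a fully missing
#' row.
#'
#' @param x an [expression_matrix].
#' @param method `"zero"` or `"row_mean"`.
#' @return An [expression_matrix] with an all-`FALSE` missing mask.
#' @export
impute_missing <- function(x, method = c("zero", "row_mean")) {
  stopifnot(inherits(x, "expression_matrix"))
  method <- match.arg(method)
  v <- x$values
  m <- x$missing_mask
  if (any(m)) {
    if (method == "zero") {
      v[m] <- 0
    } else {
      all_missing <- rowSums(!m) == 0L
      if (any(all_missing)) {
        stop("row entirely missing, cannot impute row mean: ",
             x$row_ids[which(all_missing)[1L]])
      }
      rm_ <- rowSums(ifelse(m, 0, v)) / rowSums(!m)
      idx <- which(m, arr.ind = TRUE)
      v[idx] <- rm_[idx[, 1L]]
    }
  }
  expression_matrix(v, x$row_ids, x$gene_ids, x$condition_ids,
                    matrix(FALSE, nrow(v), ncol(v)))
}
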