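#' Validate an expression matrix
#'
#' Checks the invariants every downstream scorer relies on: a numeric
#' gene-by-sample matrix with unique gene and sample identifiers and
#' finite, non-negative values (FPKM-scale expression).
#'
#' @param mat Numeric matrix, genes as rows, with `rownames` (gene ids)
#'   and `colnames` (sample ids).
#' @return `mat`, invisibly, if valid; otherwise an error describing the
#'   first violated invariant (naming duplicates or cell coordinates).
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  dup_g <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup_g) > 0L) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dup_s) > 0L) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid expression value %s at gene '%s', sample '%s' (must be finite and >= 0)",
      format(mat[bad[1, 1], bad[1, 2]]),
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]), call. = FALSE)
  }
  invisible(mat)
}

#' Read a gene-by-sample expression table
#'
#' Reads a delimited text table whose first column holds gene identifiers
#' and whose header row holds sample identifiers (or the transpose, with
#' `genes_as_rows = FALSE`).  The in-memory orientation is always
#' genes-as-rows.  Missing, non-numeric or negative cells are rejected
#' with their coordinates; no imputation is performed.
#'
#' @param path Path to the table.
#' @param delimiter Field separator (default tab).
#' @param genes_as_rows If `FALSE` the file is sample-by-gene and is
#'   transposed after reading.
#' @return Validated numeric matrix, genes as rows.
#' @export
read_expression <- function(path, delimiter = "\t", genes_as_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) {
    stop("expression table needs an identifier column plus at least one data column",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  cols <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)), USE.NAMES = FALSE))
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(cols))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 raw[bad[1, 1], bad[1, 2] + 1L], ids[bad[1, 1]],
                 cols[bad[1, 2]], path), call. = FALSE)
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative expression value %s at row '%s', column '%s' in %s",
                 format(vals[neg[1, 1], neg[1, 2]]), ids[neg[1, 1]],
                 cols[neg[1, 2]], path), call. = FALSE)
  }
  dimnames(vals) <- list(ids, cols)
  if (!genes_as_rows) vals <- t(vals)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: first column `gene_id`, header row of
#' sample identifiers.  Values are written with full precision so that a
#' read/write round trip is exact.
#'
#' @inheritParams validate_expression_matrix
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_expression <- function(mat, path, delimiter = "\t") {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample-to-group label table
#'
#' Two-column delimited table with header `sample_id`, `group`.  The
#' group tag set is open (any strings); exact duplicate rows are
#' deduplicated, conflicting assignments are an error.
#'
#' @param path Path to the label table.
#' @param delimiter Field separator (default tab).
#' @return Named character vector: `names` are sample ids, values group
#'   tags.
#' @export
read_group_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("label table needs two columns: sample_id, group",
                          call. = FALSE)
  df <- unique(df[, 1:2])
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  if (length(dup) > 0L) {
    stop("conflicting group assignment for sample(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a sample-to-group label table
#'
#' @param labels Named character vector (sample id -> group tag).
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_group_labels <- function(labels, path, delimiter = "\t") {
  utils::write.table(
    data.frame(sample_id = names(labels), group = unname(labels)),
    path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a matrix and label table describe the same samples
#'
#' @inheritParams validate_expression_matrix
#' @param labels Named character vector as from [read_group_labels()].
#' @return Invisibly `TRUE`; errors reporting the symmetric difference
#'   of the two sample sets otherwise.
#' @export
check_samples_match <- function(mat, labels) {
  only_m <- setdiff(colnames(mat), names(labels))
  only_l <- setdiff(names(labels), colnames(mat))
  if (length(only_m) > 0L || length(only_l) > 0L) {
    stop("sample sets differ; only in matrix: {",
         paste(only_m, collapse = ", "), "}; only in labels: {",
         paste(only_l, collapse = ", "), "}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-transform expression values
#'
#' Replaces every value v by log2(v + offset).  Monotone per gene, so
#' rank-based results are unchanged; kernel and boundary results operate
#' on the transformed scale.  Off by default throughout the package:
#' FPKM values are used raw unless explicitly transformed.
#'
#' @inheritParams validate_expression_matrix
#' @param offset Strictly positive pseudo-value added before the log
#'   (default 1, so zero expression maps to 0).
#' @return Transformed matrix with the same dimnames.
#' @export
log_transform <- function(mat, offset = 1) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("offset must be a single positive number", call. = FALSE)
  }
  validate_expression_matrix(mat)
  out <- log2(mat + offset)
  dimnames(out) <- dimnames(mat)
  out
}

# Split samples of one gene into the two group-restricted value vectors
# used by every scorer. Errors name the offending gene/group.
gene_two_sample <- function(mat, labels, gene, group_a, group_b) {
  if (!gene %in% rownames(mat)) stop("unknown gene: ", gene, call. = FALSE)
  check_samples_match(mat, labels)
  v <- mat[gene, ]
  x <- unname(v[names(labels)[labels == group_a]])
  y <- unname(v[names(labels)[labels == group_b]])
  if (length(x) < 2L) stop(sprintf("group '%s' has < 2 samples (gene '%s')",
                                   group_a, gene), call. = FALSE)
  if (length(y) < 2L) stop(sprintf("group '%s' has < 2 samples (gene '%s')",
                                   group_b, gene), call. = FALSE)
  list(x = x, y = y)
}
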