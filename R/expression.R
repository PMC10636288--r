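#' Construct an expression matrix object
#'
#' The canonical container for gene-expression data: a samples x genes
#' numeric matrix of log2-scale values with unique sample and gene
#' identifiers. Values are assumed already normalized/log2-transformed;
#' the package never re-normalizes.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param gene_ids Character vector of unique gene identifiers.
#' @return An object of class `expression_matrix` (a numeric matrix with
#'   dimnames and a class attribute).
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(sample_ids))
    stop("row count (", nrow(values), ") != number of sample_ids (",
         length(sample_ids), ")")
  if (ncol(values) != length(gene_ids))
    stop("column count (", ncol(values), ") != number of gene_ids (",
         length(gene_ids), ")")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at sample '", sample_ids[bad[1L]],
         "', gene '", gene_ids[bad[2L]], "'")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x), " samples x ", ncol(x), " genes\n",
      sep = "")
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Reads the canonical tab/comma-separated dialect: one header row, first
#' column holding identifiers (`sample_id` for `samples_in_rows`). The
#' loader rejects missing or non-numeric cells by default, naming the
#' offending cell; `impute = "mean"` replaces missing entries by the
#' per-gene mean instead.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`;
#'   the latter is transposed on load so the result is always samples x
#'   genes.
#' @param impute `"reject"` (default) or `"mean"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows",
                                                   "genes_in_rows"),
                                   impute = c("reject", "mean")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "NaN", ""))
  if (ncol(dt) < 2L) stop("expected an identifier column plus >=1 data column")
  row_ids <- as.character(dt[[1L]])
  col_ids <- colnames(dt)[-1L]
  if (anyDuplicated(row_ids))
    stop("duplicate identifiers in first column of ", path)
  if (anyDuplicated(col_ids))
    stop("duplicate identifiers in header of ", path)
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(vals),
                                              dim(vals)))) & !is.na(vals),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-numeric value at row '", row_ids[bad[1L, 1L]],
           "', column '", col_ids[bad[1L, 2L]], "' of ", path)
    storage.mode(vals) <- "double"
  }
  if (anyNA(vals)) {
    if (impute == "reject") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing value (NA) at row '", row_ids[bad[1L]], "', column '",
           col_ids[bad[2L]], "' of ", path, " (impute = \"reject\")")
    }
    # mean-impute within each gene (column for samples_in_rows, row otherwise)
    if (orientation == "genes_in_rows") vals <- t(vals)
    mu <- matrixStats::colMeans2(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- mu[idx[, 2L]]
    if (orientation == "genes_in_rows") vals <- t(vals)
  }
  if (orientation == "genes_in_rows") {
    expression_matrix(t(vals), sample_ids = col_ids, gene_ids = row_ids)
  } else {
    expression_matrix(vals, sample_ids = row_ids, gene_ids = col_ids)
  }
}

#' Write an expression matrix in the canonical dialect
#'
#' Tab-separated, UTF-8, '.' decimal, first column `sample_id`; the exact
#' inverse of [read_expression_matrix()] with default orientation.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  # %.17g guarantees doubles survive the text round trip bit-for-bit
  # (fwrite tops out at 15 significant digits)
  vals <- matrix(sprintf("%.17g", unclass(expr)), nrow = nrow(expr))
  lines <- c(paste(c("sample_id", colnames(expr)), collapse = "\t"),
             paste(rownames(expr),
                   apply(vals, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a label table
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Character vector of class labels, one per sample.
#' @param class_names Optional ordered unique label set; defaults to the
#'   sorted unique labels.
#' @return A `label_table` object (data.frame with a `class_names`
#'   attribute).
#' @export
label_table <- function(sample_ids, labels, class_names = NULL) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels differ in length")
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop("duplicate sample_id: ", dup)
  }
  if (is.null(class_names)) class_names <- sort(unique(labels))
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) stop("class_names must be unique")
  unknown <- setdiff(labels, class_names)
  if (length(unknown) > 0L)
    stop("label(s) outside class_names: ", paste(unknown, collapse = ", "))
  if (length(class_names) < 2L) stop("need >= 2 classes")
  out <- data.frame(sample_id = sample_ids, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "class_names") <- class_names
  class(out) <- c("label_table", "data.frame")
  out
}

#' Ordered class names of a label table
#' @param labels A [label_table()].
#' @return Character vector of class names, in table order.
#' @export
class_names <- function(labels) attr(labels, "class_names")

#' Read a sample-to-subtype label table
#'
#' @param path Two-column delimited file (sample_id, label) with header.
#' @param class_order Optional explicit class ordering; labels outside it
#'   are an error.
#' @return A [label_table()].
#' @export
read_labels <- function(path, class_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("expected two columns (sample_id, label) in ", path)
  label_table(dt[[1L]], dt[[2L]], class_names = class_order)
}

#' Write a label table in the canonical dialect
#' @param labels A [label_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels[, c("sample_id", "label")], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

# Internal: align a label table to an expression matrix's samples.
# Returns the label character vector in expr row order.
align_labels <- function(expr, labels) {
  idx <- match(rownames(expr), labels$sample_id)
  if (anyNA(idx)) {
    miss <- rownames(expr)[is.na(idx)]
    stop("samples missing from label table: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "")
  }
  labels$label[idx]
}
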