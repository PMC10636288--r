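#' Per-gene log2 fold change between a group and the rest
#'
#' Values are assumed already on the log2 scale, so the fold change is a
#' difference of group means: `mean(in_group) - mean(rest)` per gene.
#'
#' @param expr An [expression_matrix()].
#' @param in_group Logical, integer, or character (sample id) subset;
#'   must be non-empty and a strict subset of the samples.
#' @return Named numeric vector, one value per gene.
#' @export
log2_fold_change <- function(expr, in_group) {
  sel <- resolve_samples(expr, in_group)
  if (!any(sel)) stop("in_group is empty")
  if (all(sel)) stop("in_group must be a strict subset (rest group is empty)")
  x <- unclass(expr)
  stats::setNames(matrixStats::colMeans2(x, rows = which(sel)) -
                    matrixStats::colMeans2(x, rows = which(!sel)),
                  colnames(expr))
}

# Internal: normalize a sample subset selector to a logical mask
resolve_samples <- function(expr, in_group) {
  n <- nrow(expr)
  if (is.logical(in_group)) {
    stopifnot(length(in_group) == n)
    in_group
  } else if (is.character(in_group)) {
    idx <- match(in_group, rownames(expr))
    if (anyNA(idx)) stop("unknown sample id(s) in in_group")
    seq_len(n) %in% idx
  } else {
    seq_len(n) %in% as.integer(in_group)
  }
}

# Internal: vectorized Welch two-sample t-test across gene columns.
# Degenerate convention: zero standard error with equal means -> p = 1
# (constant gene); zero standard error with unequal means -> p = 0.
welch_t_columns <- function(x, sel) {
  i1 <- which(sel); i2 <- which(!sel)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples")
  m1 <- matrixStats::colMeans2(x, rows = i1)
  m2 <- matrixStats::colMeans2(x, rows = i2)
  v1 <- matrixStats::colVars(x, rows = i1)
  v2 <- matrixStats::colVars(x, rows = i2)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- se2 == 0
  p[zero_se] <- ifelse(abs(m1[zero_se] - m2[zero_se]) < .Machine$double.eps^0.5,
                       1, 0)
  p
}

# Internal: vectorized two-sided Wilcoxon (Mann-Whitney) rank-sum test,
# normal approximation with tie correction and continuity correction
# (matches stats::wilcox.test(exact = FALSE, correct = TRUE)).
# All-tied column (sigma = 0) -> p = 1.
wilcoxon_columns <- function(x, sel) {
  i1 <- which(sel)
  n1 <- length(i1); n <- nrow(x); n2 <- n - n1
  if (n1 < 1L || n2 < 1L) stop("both groups need >= 1 sample")
  p <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    r <- rank(col)
    u <- sum(r[i1]) - n1 * (n1 + 1) / 2 - n1 * n2 / 2
    nt <- rle(sort(col))$lengths
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - sign(u) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1L))
  p
}

#' One-vs-rest differential tests for a single class
#'
#' For each gene, compares samples of `class_name` against all remaining
#' samples with a Welch two-sample t-test and a two-sided Wilcoxon
#' rank-sum test (normal approximation, tie and continuity correction),
#' and reports the log2 fold change (difference of log2-scale means).
#'
#' @param expr An [expression_matrix()].
#' @param labels A [label_table()] covering the samples of `expr`.
#' @param class_name The class forming the "in" group; both groups must
#'   contain at least two samples.
#' @return A data.frame with columns `class`, `gene_id`, `log2fc`,
#'   `p_t`, `p_w`, one row per gene in matrix order.
#' @export
differential_test_one_vs_rest <- function(expr, labels, class_name) {
  y <- align_labels(expr, labels)
  if (!class_name %in% class_names(labels))
    stop("unknown class: ", class_name)
  sel <- y == class_name
  if (sum(sel) < 2L || sum(!sel) < 2L)
    stop("class '", class_name, "' or its complement has < 2 samples")
  x <- unclass(expr)
  data.frame(class = class_name,
             gene_id = colnames(expr),
             log2fc = as.numeric(log2_fold_change(expr, sel)),
             p_t = welch_t_columns(x, sel),
             p_w = wilcoxon_columns(x, sel),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted values ("Q values"): each
#' adjusted value is >= its p-value, <= 1, and monotone in the sorted
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(!is.finite(p_values)))
    stop("p-values must be finite")
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes
#'
#' The discriminative gene filter: for every class, a one-vs-rest
#' comparison computes per-gene Welch-t and Wilcoxon p-values and the
#' log2 fold change; each test's p-values are Benjamini-Hochberg
#' adjusted within that comparison; a gene is selected for a comparison
#' iff `|log2fc| > fc_threshold` AND both adjusted values are below
#' `q_threshold`. The final gene list is the union over comparisons,
#' deduplicated, in original gene order.
#'
#' @param expr An [expression_matrix()].
#' @param labels A [label_table()] (>= 2 classes).
#' @param fc_threshold Absolute log2-fold-change gate (default 1).
#' @param q_threshold FDR gate applied to both tests (default 0.05).
#' @return A list of class `deg_result` with elements `genes` (ordered
#'   character vector of selected gene ids) and `table` (data.frame with
#'   columns class, gene_id, log2fc, p_t, q_t, p_w, q_w, selected).
#' @export
select_degs <- function(expr, labels, fc_threshold = 1, q_threshold = 0.05) {
  if (fc_threshold < 0 || q_threshold <= 0)
    stop("thresholds must be positive")
  cls <- class_names(labels)
  if (length(cls) < 2L) stop("need >= 2 classes")
  tabs <- lapply(cls, function(cl) {
    tab <- differential_test_one_vs_rest(expr, labels, cl)
    tab$q_t <- bh_adjust(tab$p_t)
    tab$q_w <- bh_adjust(tab$p_w)
    tab$selected <- abs(tab$log2fc) > fc_threshold &
      tab$q_t < q_threshold & tab$q_w < q_threshold
    tab[, c("class", "gene_id", "log2fc", "p_t", "q_t", "p_w", "q_w",
            "selected")]
  })
  table <- do.call(rbind, tabs)
  hits <- unique(table$gene_id[table$selected])
  genes <- colnames(expr)[colnames(expr) %in% hits]
  structure(list(genes = genes, table = table,
                 fc_threshold = fc_threshold, q_threshold = q_threshold),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("<deg_result> ", length(x$genes), " genes selected (|log2FC| > ",
      x$fc_threshold, ", Q < ", x$q_threshold, ", both tests)\n", sep = "")
  invisible(x)
}

#' Write a DEG table as TSV
#' @param deg A `deg_result` from [select_degs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  data.table::fwrite(deg$table, path, sep = "\t", quote = FALSE)
  invisible(path)
}
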