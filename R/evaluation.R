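#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of truth class `i` predicted as class
#' `j`; rows are truth, columns prediction, both ordered by
#' `class_names`.
#'
#' @param y_true,y_pred Equal-length label vectors; every label must
#'   appear in `class_names`.
#' @param class_names Ordered class set.
#' @return Integer matrix with dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  unknown <- setdiff(c(y_true, y_pred), class_names)
  if (length(unknown) > 0L)
    stop("label(s) not in class_names: ", paste(unknown, collapse = ", "))
  tab <- table(factor(y_true, levels = class_names),
               factor(y_pred, levels = class_names))
  m <- matrix(as.integer(tab), nrow = length(class_names),
              dimnames = list(truth = class_names, prediction = class_names))
  m
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest per class: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/n`; plus overall accuracy
#' (`trace/n`) and macro averages. The macro accuracy is the mean
#' per-class recall ("average accuracy per class"); classes absent from
#' the truth have undefined sensitivity and are skipped by the macro
#' averages (their count is reported in `n_undefined`).
#'
#' @param confusion Square integer matrix (rows truth, columns
#'   prediction).
#' @return A `metrics_report` list: `confusion`, `per_class`
#'   (data.frame), `overall_accuracy`, `macro_accuracy`,
#'   `macro_sensitivity`, `macro_specificity`, `n`, `n_undefined`.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("negative confusion entries")
  n <- sum(confusion)
  if (n == 0L) stop("all-zero confusion matrix")
  cls <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NaN)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NaN)
  acc_c <- (tp + tn) / n
  per_class <- data.frame(class = cls, tp = tp, fn = fn, fp = fp, tn = tn,
                          sensitivity = sens, specificity = spec,
                          accuracy = acc_c, row.names = NULL)
  structure(list(confusion = confusion, per_class = per_class,
                 overall_accuracy = sum(tp) / n,
                 macro_accuracy = mean(sens, na.rm = TRUE),
                 macro_sensitivity = mean(sens, na.rm = TRUE),
                 macro_specificity = mean(spec, na.rm = TRUE),
                 n = n, n_undefined = sum(is.nan(sens)) + sum(is.nan(spec))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n = ", x$n,
      sprintf("; overall accuracy %.4f; macro accuracy %.4f",
              x$overall_accuracy, x$macro_accuracy),
      sprintf("; macro sensitivity %.4f; macro specificity %.4f\n",
              x$macro_sensitivity, x$macro_specificity), sep = "")
  print(x$confusion)
  invisible(x)
}

#' Default model factory for cross-validation
#'
#' Wraps [fit_adler()] for a fixed architecture so [cross_validate()]
#' can re-fit it inside every training fold.
#'
#' @param ind An `adler_individual`.
#' @param patience,batch_size Training controls.
#' @return `function(expr_train, labels, seed)` returning a fitted
#'   model with a `predict` method.
#' @export
adler_factory <- function(ind, patience = 50L, batch_size = 32L) {
  force(ind)
  function(expr_train, labels, seed)
    fit_adler(expr_train, labels, ind, patience = patience,
              batch_size = batch_size, seed = seed)
}

#' Leakage-safe stratified cross-validation
#'
#' Splits the samples into `k` stratified folds (deterministic given
#' `seed`); within each fold's training part only, optionally performs
#' gene selection (the DEG filter, or a rank-based top-n selector),
#' fits the model, and scores the held-out fold. Setting
#' `leak_selection = TRUE` deliberately performs selection once on the
#' full data — a negative control quantifying selection bias, never a
#' mode to use for real results.
#'
#' @param expr An [expression_matrix()].
#' @param labels A [label_table()].
#' @param model_factory `function(expr_train, labels, seed) -> model`
#'   whose `predict(model, expr)` returns `list(prob, label)`; see
#'   [adler_factory()].
#' @param k Number of folds (`k == n` is leave-one-out).
#' @param seed Integer seed (folds + per-fold model seeds).
#' @param selector `"none"` (default), `"deg"` (FDR+fold-change gate;
#'   falls back to the `top_n` smallest-p genes if the gate selects
#'   nothing), or `"top_n"` (always the `top_n` smallest min-p genes).
#' @param fc_threshold,q_threshold DEG gate parameters.
#' @param top_n Gene count for the rank-based selector/fallback.
#' @param leak_selection Perform selection on the full data (negative
#'   control)?
#' @return List of class `cv_result`: `fold_reports` (one
#'   [classification_metrics()] per fold), `pooled` (concatenated
#'   predictions), `folds`, `predictions` (data.frame), `selected_genes`
#'   (per fold).
#' @export
cross_validate <- function(expr, labels, model_factory, k = 5L, seed = 1L,
                           selector = c("none", "deg", "top_n"),
                           fc_threshold = 1, q_threshold = 0.05,
                           top_n = 10L, leak_selection = FALSE) {
  selector <- match.arg(selector)
  y <- align_labels(expr, labels)
  folds <- stratified_folds(y, k, seed = derive_seed(seed, "cv_folds"))
  x <- unclass(expr)
  cls <- class_names(labels)

  select_genes <- function(expr_sub, labels) {
    if (selector == "none") return(colnames(expr_sub))
    deg <- select_degs(expr_sub, labels, fc_threshold, q_threshold)
    if (selector == "deg" && length(deg$genes) > 0L) return(deg$genes)
    # rank-based: top_n genes by smallest p-value across comparisons
    minp <- tapply(pmin(deg$table$p_t, deg$table$p_w), deg$table$gene_id, min)
    names(sort(minp))[seq_len(min(top_n, length(minp)))]
  }

  leaked_genes <- if (leak_selection) select_genes(expr, labels) else NULL
  pred_all <- character(length(y))
  fold_reports <- vector("list", k)
  selected <- vector("list", k)
  for (fd in seq_len(k)) {
    tr <- folds != fd
    expr_tr <- expression_matrix(x[tr, , drop = FALSE])
    genes <- leaked_genes %||% select_genes(expr_tr, labels)
    selected[[fd]] <- genes
    expr_tr <- expression_matrix(x[tr, genes, drop = FALSE])
    expr_te <- expression_matrix(x[!tr, genes, drop = FALSE])
    model <- model_factory(expr_tr, labels,
                           seed = derive_seed(seed, paste0("fold", fd)))
    pr <- predict(model, expr_te)
    pred_all[!tr] <- pr$label
    fold_reports[[fd]] <- classification_metrics(
      confusion_matrix(y[!tr], pr$label, cls))
  }
  pooled <- classification_metrics(confusion_matrix(y, pred_all, cls))
  structure(list(fold_reports = fold_reports, pooled = pooled, folds = folds,
                 predictions = data.frame(sample_id = rownames(expr),
                                          truth = y, predicted = pred_all,
                                          fold = folds),
                 selected_genes = selected, k = k, seed = seed,
                 leak_selection = leak_selection),
            class = "cv_result")
}

#' Rank marker genes per predicted class
#'
#' For every class present in the predictions, genes are ranked by
#' ascending one-vs-rest Wilcoxon rank-sum p-value (ties broken by
#' decreasing `|log2fc|`, then gene id) and the `top_n` head is
#' returned. Constant genes get p = 1 and sink to the bottom.
#'
#' @param expr An [expression_matrix()].
#' @param predicted_labels Character vector, one label per sample (at
#'   least two distinct classes must be present).
#' @param top_n Genes per class (full ranking if larger than the gene
#'   count).
#' @return Named list (class -> data.frame with columns rank, gene_id,
#'   p, log2fc).
#' @export
rank_marker_genes <- function(expr, predicted_labels, top_n = 10L) {
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(predicted_labels) == nrow(expr))
  present <- unique(predicted_labels)
  if (length(present) < 2L)
    stop("marker ranking needs >= 2 predicted classes")
  x <- unclass(expr)
  out <- lapply(sort(present), function(cl) {
    sel <- predicted_labels == cl
    p <- wilcoxon_columns(x, sel)
    lfc <- as.numeric(log2_fold_change(expr, sel))
    ord <- order(p, -abs(lfc), colnames(expr))
    head_n <- min(top_n, ncol(expr))
    data.frame(rank = seq_len(head_n), gene_id = colnames(expr)[ord][seq_len(head_n)],
               p = p[ord][seq_len(head_n)], log2fc = lfc[ord][seq_len(head_n)],
               row.names = NULL)
  })
  stats::setNames(out, sort(present))
}
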