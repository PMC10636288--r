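# Confusion matrices, macro metrics, cross-validation, marker ranking.

test_that("confusion matrix: hand count, invariance, validation", {
  m <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(unname(m), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  perfect <- confusion_matrix(c("A", "B", "A"), c("A", "B", "A"), c("A", "B"))
  expect_identical(unname(perfect), diag(c(2L, 1L)))
  # sample-order invariance
  set.seed(1)
  y1 <- sample(c("A", "B", "C"), 60, TRUE)
  y2 <- sample(c("A", "B", "C"), 60, TRUE)
  perm <- sample(60)
  expect_identical(confusion_matrix(y1, y2, c("A", "B", "C")),
                   confusion_matrix(y1[perm], y2[perm], c("A", "B", "C")))
  expect_error(confusion_matrix(c("A", "X"), c("A", "A"), c("A", "B")),
               "not in class_names")
  expect_error(confusion_matrix(c("A", "B"), "A", c("A", "B")), "length")
})

test_that("metrics: binary hand values and degenerate contracts", {
  conf <- matrix(c(40L, 5L, 10L, 45L), 2, 2,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  r <- classification_metrics(conf)
  expect_equal(r$per_class$sensitivity[1L], 0.8, tolerance = 1e-12)
  expect_equal(r$per_class$specificity[1L], 0.9, tolerance = 1e-12)
  expect_equal(r$overall_accuracy, 0.85, tolerance = 1e-12)
  ident <- classification_metrics(diag(c(3L, 4L, 5L)))
  expect_equal(ident$overall_accuracy, 1)
  expect_equal(ident$macro_accuracy, 1)
  expect_equal(ident$macro_specificity, 1)
  # class absent from truth: NaN-flagged and skipped by the macro mean
  conf0 <- matrix(c(5L, 0L, 3L, 0L), 2, 2,
                  dimnames = list(c("A", "B"), c("A", "B")))
  r0 <- classification_metrics(conf0)
  expect_true(is.nan(r0$per_class$sensitivity[2L]))
  expect_equal(r0$macro_accuracy, 5 / 8)
  expect_gte(r0$n_undefined, 1L)
  expect_error(classification_metrics(matrix(0L, 2, 2)), "all-zero")
})

test_that("metrics agree with a per-sample counting oracle", {
  set.seed(33)
  cls <- c("C1", "C2", "C3", "C4")
  for (rep_i in 1:50) {
    y <- sample(cls, 40, TRUE)
    p <- sample(cls, 40, TRUE)
    r <- classification_metrics(confusion_matrix(y, p, cls))
    expect_equal(r$overall_accuracy, mean(y == p), tolerance = 1e-12)
    for (cl in cls) {
      if (any(y == cl))
        expect_equal(r$per_class$sensitivity[match(cl, cls)],
                     mean(p[y == cl] == cl), tolerance = 1e-12)
      if (any(y != cl))
        expect_equal(r$per_class$specificity[match(cl, cls)],
                     mean(p[y != cl] != cl), tolerance = 1e-12)
    }
  }
})

test_that("overall equals macro accuracy exactly on balanced truth", {
  set.seed(9)
  y <- rep(c("A", "B"), each = 30)
  p <- sample(c("A", "B"), 60, TRUE)
  r <- classification_metrics(confusion_matrix(y, p, c("A", "B")))
  expect_equal(r$overall_accuracy, r$macro_accuracy, tolerance = 1e-12)
})

test_that("stratified folds: determinism, stratification, LOO, errors", {
  y <- rep(c("A", "B", "C"), times = c(12, 9, 6))
  f1 <- stratified_folds(y, 3L, seed = 4L)
  f2 <- stratified_folds(y, 3L, seed = 4L)
  expect_identical(f1, f2)
  expect_false(identical(f1, stratified_folds(y, 3L, seed = 5L)))
  for (k in 1:3)
    expect_identical(as.integer(table(y[f1 == k])), c(4L, 3L, 2L))
  # leave-one-out boundary: singleton folds
  y8 <- rep(c("A", "B"), 4)
  f <- stratified_folds(y8, 8L, seed = 1L)
  expect_identical(sort(f), 1:8)
  expect_error(stratified_folds(y8, 9L), "exceeds")
  expect_error(stratified_folds(rep(c("A", "B"), c(2, 10)), 4L),
               "smaller k")
})

test_that("cross_validate pools predictions and re-fits selection per fold", {
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 2L, n_per_class = 25L, n_genes = 60L,
                   n_informative_per_class = 5L, effect_size = 3.0,
                   seed = 19L))
  ind <- individual(40L, "adam", 1e-2,
                    list(list(width = 8L, activation = "tanh", dropout = 0,
                              batchnorm = FALSE, l1 = 0, l2 = 0)))
  cv <- cross_validate(ds$expression, ds$labels, adler_factory(ind),
                       k = 4L, seed = 2L, selector = "deg")
  expect_identical(cv$pooled$n, 50L) # every sample predicted exactly once
  expect_length(cv$fold_reports, 4L)
  expect_identical(sum(vapply(cv$fold_reports, `[[`, 0L, "n")), 50L)
  expect_gte(cv$pooled$overall_accuracy, 0.9) # separable world
  # fold-specific gene sets exist (selection happened inside folds)
  expect_length(cv$selected_genes, 4L)
  cv2 <- cross_validate(ds$expression, ds$labels, adler_factory(ind),
                        k = 4L, seed = 2L, selector = "deg")
  expect_identical(cv$folds, cv2$folds) # deterministic folds
  expect_identical(cv$predictions$predicted, cv2$predictions$predicted)
})

test_that("marker ranking surfaces planted genes and orders sanely", {
  # 4-class world: each class's planted block is unique to it, so its
  # one-vs-rest ranking must surface exactly that block
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 4L, n_per_class = 50L, n_genes = 200L,
                   n_informative_per_class = 10L, effect_size = 3.0,
                   seed = 25L))
  mk <- rank_marker_genes(ds$expression, ds$labels$label, top_n = 10L)
  for (cl in paste0("C", 1:4))
    expect_setequal(mk[[cl]]$gene_id, ds$truth_informative[[cl]])
  expect_true(all(diff(mk$C1$p) >= 0))
  # top_n beyond gene count -> full ranking
  mk_all <- rank_marker_genes(ds$expression, ds$labels$label, top_n = 999L)
  expect_identical(nrow(mk_all$C1), 200L)
  # constant gene sinks to the bottom with p = 1
  x <- unclass(ds$expression)
  x[, 1L] <- 5
  mk2 <- rank_marker_genes(expression_matrix(x), ds$labels$label,
                           top_n = 200L)
  expect_identical(mk2$C1$gene_id[200L], colnames(x)[1L])
  expect_equal(mk2$C1$p[200L], 1)
  expect_error(rank_marker_genes(ds$expression,
                                 rep("C1", nrow(ds$expression))), ">= 2")
})
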