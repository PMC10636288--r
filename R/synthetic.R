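#' Specification for a synthetic multiclass expression dataset
#'
#' Describes the generative world used throughout the test-suite: iid
#' Gaussian log2-intensity background around a common baseline, with a
#' disjoint block of class-informative genes per class whose mean is
#' shifted upward by `effect_size` in that class only. This emulates the
#' marker structure of subtype-labelled microarray cohorts; it does not
#' simulate platform/batch effects, gene-gene correlation or library
#' size.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Samples per class (balanced by default).
#' @param n_genes Total genes.
#' @param n_informative_per_class Planted informative genes per class;
#'   `n_informative_per_class * n_classes <= n_genes`.
#' @param effect_size Mean shift on the log2 scale (>= 0).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param baseline Background mean log2 intensity.
#' @param imbalance Ratio of largest to smallest class size (>= 1);
#'   class sizes interpolate linearly between the extremes.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 4L, n_per_class = 50L,
                           n_genes = 1000L, n_informative_per_class = 10L,
                           effect_size = 2.0, noise_sd = 1.0,
                           baseline = 7.0, imbalance = 1.0, seed = 1L) {
  spec <- list(n_classes = as.integer(n_classes),
               n_per_class = as.integer(n_per_class),
               n_genes = as.integer(n_genes),
               n_informative_per_class = as.integer(n_informative_per_class),
               effect_size = as.numeric(effect_size),
               noise_sd = as.numeric(noise_sd),
               baseline = as.numeric(baseline),
               imbalance = as.numeric(imbalance),
               seed = as.integer(seed))
  if (spec$n_classes < 2L) stop("n_classes must be >= 2")
  if (spec$n_per_class < 1L) stop("n_per_class must be >= 1")
  if (spec$n_informative_per_class * spec$n_classes > spec$n_genes)
    stop("n_informative_per_class * n_classes exceeds n_genes")
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0")
  if (spec$imbalance < 1) stop("imbalance must be >= 1")
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a multiclass expression dataset with planted markers
#'
#' Background entries are `Normal(baseline, noise_sd)` iid; the
#' informative block of class `c` gains `+effect_size` in samples of
#' class `c` only. Class labels are `C1..Ck`; gene ids `g0001..`;
#' informative genes are the first `n_informative_per_class * n_classes`
#' gene columns, blocked by class (truth is returned, and the blocks are
#' disjoint by construction).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with elements
#'   `expression` ([expression_matrix()]), `labels` ([label_table()]) and
#'   `truth_informative` (named list: class -> character vector of gene
#'   ids).
#' @export
generate_classification_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- spec$n_classes
  # class sizes: linear interpolation between n_per_class and
  # n_per_class / imbalance, largest class first
  sizes <- round(seq(spec$n_per_class, spec$n_per_class / spec$imbalance,
                     length.out = k))
  sizes <- pmax(sizes, 1L)
  n <- sum(sizes)
  classes <- paste0("C", seq_len(k))
  y <- rep(classes, times = sizes)
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  x <- matrix(stats::rnorm(n * spec$n_genes, mean = spec$baseline,
                           sd = spec$noise_sd),
              nrow = n, ncol = spec$n_genes)
  truth <- stats::setNames(vector("list", k), classes)
  m <- spec$n_informative_per_class
  for (ci in seq_len(k)) {
    cols <- ((ci - 1L) * m + 1L):(ci * m)
    if (m > 0L) {
      x[y == classes[ci], cols] <- x[y == classes[ci], cols] + spec$effect_size
      truth[[ci]] <- gene_ids[cols]
    } else truth[[ci]] <- character(0L)
  }
  sample_ids <- sprintf("s%04d", seq_len(n))
  out <- list(expression = expression_matrix(x, sample_ids, gene_ids),
              labels = label_table(sample_ids, y, class_names = classes),
              truth_informative = truth,
              spec = spec)
  class(out) <- "synthetic_dataset"
  out
}

#' Generate a null dataset (labels independent of expression)
#'
#' Pure background: every gene is `Normal(baseline, noise_sd)` in every
#' class, labels are assigned round-robin, and `truth_informative` is
#' empty. Any classifier's expected balanced accuracy on this data is
#' `1/n_classes`, and per-gene two-sample test p-values are Uniform(0,1).
#'
#' @param n_samples Total samples (>= 2 * n_classes).
#' @param n_genes Number of genes.
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @param baseline,noise_sd Background distribution parameters.
#' @return A `synthetic_dataset` with empty `truth_informative`.
#' @export
generate_null_dataset <- function(n_samples, n_genes, n_classes = 4L,
                                  seed = 1L, baseline = 7.0, noise_sd = 1.0) {
  n_classes <- as.integer(n_classes)
  if (n_samples < 2L * n_classes)
    stop("n_samples must be >= 2 * n_classes")
  per <- ceiling(n_samples / n_classes)
  spec <- synthetic_spec(n_classes = n_classes, n_per_class = per,
                         n_genes = n_genes, n_informative_per_class = 0L,
                         effect_size = 0, noise_sd = noise_sd,
                         baseline = baseline, seed = seed)
  ds <- generate_classification_dataset(spec)
  if (nrow(ds$expression) > n_samples) { # trim to requested size evenly
    keep <- sort(unlist(lapply(split(seq_len(nrow(ds$expression)),
                                     ds$labels$label),
                               utils::head,
                               n = ceiling(n_samples / n_classes))))
    keep <- keep[seq_len(n_samples)]
    ds$expression <- expression_matrix(unclass(ds$expression)[keep, ,
                                                              drop = FALSE])
    ds$labels <- label_table(ds$labels$sample_id[keep],
                             ds$labels$label[keep],
                             class_names = class_names(ds$labels))
  }
  ds$truth_informative <- stats::setNames(
    rep(list(character(0L)), n_classes), paste0("C", seq_len(n_classes)))
  ds
}

#' Write a synthetic dataset to disk
#'
#' Emits the canonical TSV pair (expression matrix + labels) plus a JSON
#' file recording the generating spec and the planted truth.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(ds$expression, paths[["expression"]])
  write_labels(ds$labels, paths[["labels"]])
  jsonlite::write_json(list(spec = unclass(ds$spec),
                            truth_informative = ds$truth_informative),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
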